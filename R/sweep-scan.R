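#' Windowed Fst between two populations
#'
#' Default estimator is Hudson's (1992) ratio-of-sums: per usable site
#' (both populations with at least 2 genotyped alleles) the numerator
#' `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and denominator
#' `p1(1-p2) + p2(1-p1)` are summed across the window before taking the
#' ratio, which is robust to unequal sample sizes. A Weir-Cockerham (1984)
#' variant (haploid-frequency form with observed heterozygosity) is
#' available behind the `estimator` flag.
#'
#' @param gm A `genotype_matrix`.
#' @param windows Data frame of windows (0-based half-open); pass a single
#'   row for one window.
#' @param manifest A `population_manifest`.
#' @param pop_a,pop_b Population labels (including `"cultivated"`).
#' @param estimator `"hudson"` (default) or `"wc"`.
#' @return Numeric vector of window Fst values; `NA` where no usable site
#'   exists. Values may be slightly negative; [pbs()] clamps its inputs.
#' @export
window_fst <- function(gm, windows, manifest, pop_a, pop_b,
                       estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  ga <- subset_population(gm, manifest, pop_a)
  gb <- subset_population(gm, manifest, pop_b)
  aca <- allele_count_table(ga)
  acb <- allele_count_table(gb)
  comp <- fst_site_components(aca, acb, gb, ga, estimator)
  pos <- gm$sites$pos
  chrom <- gm$sites$chrom
  out <- rep(NA_real_, nrow(windows))
  for (ch in unique(windows$chrom)) {
    on_ch <- which(chrom == ch)
    wi <- which(windows$chrom == ch)
    if (!length(wi)) next
    pp <- pos[on_ch]
    cnum <- c(0, cumsum(comp$num[on_ch]))
    cden <- c(0, cumsum(comp$den[on_ch]))
    lo <- findInterval(windows$start[wi], pp) + 1L
    hi <- findInterval(windows$end[wi], pp)
    num <- cnum[hi + 1L] - cnum[lo]
    den <- cden[hi + 1L] - cden[lo]
    out[wi] <- ifelse(den > 0, num / den, NA_real_)
  }
  out
}

# Per-site numerator/denominator contributions; unusable sites contribute
# zero to both sums.
fst_site_components <- function(aca, acb, gb, ga, estimator) {
  n1 <- aca$n_alleles; n2 <- acb$n_alleles
  usable <- n1 >= 2L & n2 >= 2L
  p1 <- ifelse(usable, aca$alt_count / pmax(n1, 1L), 0)
  p2 <- ifelse(usable, acb$alt_count / pmax(n2, 1L), 0)
  if (estimator == "hudson") {
    num <- (p1 - p2)^2 -
      p1 * (1 - p1) / pmax(n1 - 1L, 1L) -
      p2 * (1 - p2) / pmax(n2 - 1L, 1L)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
  } else {
    # Weir & Cockerham 1984, two populations, allele-frequency form with
    # observed heterozygote proportions
    h1 <- colSums(ga$calls == 1L) / pmax(colSums(ga$calls >= 0L), 1L)
    h2 <- colSums(gb$calls == 1L) / pmax(colSums(gb$calls >= 0L), 1L)
    r <- 2
    nd1 <- n1 / 2; nd2 <- n2 / 2 # diploid counts
    nbar <- (nd1 + nd2) / 2
    nc <- (r * nbar - (nd1^2 + nd2^2) / (r * nbar)) / (r - 1)
    pbar <- (nd1 * p1 + nd2 * p2) / (r * nbar)
    s2 <- (nd1 * (p1 - pbar)^2 + nd2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (nd1 * h1 + nd2 * h2) / (r * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) -
                                (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- a
    den <- a + b + cc
  }
  num[!usable] <- 0
  den[!usable] <- 0
  list(num = num, den = den)
}

#' Population branch statistic
#'
#' Branch length of population A after the log transform
#' `T = -ln(1 - Fst)`: `PBS_A = (T_AB + T_AC - T_BC) / 2`. Fst values are
#' clamped to `[0, 1 - 1e-6]` (negative window estimates carry no
#' divergence signal; values at 1 would give an infinite branch).
#'
#' @param fst_ab,fst_ac,fst_bc Fst between the focal population A and the
#'   two references B, C, and between B and C. Vectorized.
#' @return PBS of population A.
#' @export
pbs <- function(fst_ab, fst_ac, fst_bc) {
  cap <- function(x) pmin(pmax(x, 0), 1 - 1e-6)
  t_ab <- -log(1 - cap(fst_ab))
  t_ac <- -log(1 - cap(fst_ac))
  t_bc <- -log(1 - cap(fst_bc))
  (t_ab + t_ac - t_bc) / 2
}

#' Bottleneck-model sweep scan for the domestication transition
#'
#' Contrasts cultivated (landrace + elite) against wild accessions per
#' window: the cultivated/wild theta-pi ratio (log-transformed with a
#' pseudocount) and cultivated Tajima's D are each standardized by their
#' genome-wide mean and standard deviation over defined windows, and a
#' window is selected when both lower-tail normal P values fall below
#' `alpha`. Windows with undefined D (no segregating site in cultivars) are
#' never selected.
#'
#' @param gm A `genotype_matrix`.
#' @param manifest A `population_manifest`.
#' @param windows Data frame from [sliding_windows()].
#' @param alpha Per-statistic significance level (default 0.05).
#' @param exclude Sample ids dropped before grouping (breeding panels often
#'   carry a few accessions excluded from scans).
#' @param delta Pseudocount stabilizing the per-site ratio (default 1e-5).
#' @return Data frame of class `scan_result`: windows plus `pi_wild`,
#'   `pi_cultivated`, `pi_ratio`, `log_ratio`, `d_cultivated`, `z_ratio`,
#'   `z_d`, `p_ratio`, `p_d`, `selected`.
#' @export
domestication_scan <- function(gm, manifest, windows, alpha = 0.05,
                               exclude = character(), delta = 1e-5) {
  if (length(exclude)) {
    keep <- !(manifest$sample %in% exclude)
    manifest <- population_manifest(manifest$sample[keep],
                                    manifest$label[keep])
    gm_keep <- gm$samples %in% manifest$sample
    gm <- genotype_matrix(gm$calls[gm_keep, , drop = FALSE], gm$sites,
                          gm$samples[gm_keep])
  }
  wild <- subset_population(gm, manifest, "wild")
  cult <- subset_population(gm, manifest, "cultivated")
  sw <- window_diversity(wild, windows)
  sc <- window_diversity(cult, windows)
  res <- windows
  res$pi_wild <- sw$theta_pi
  res$pi_cultivated <- sc$theta_pi
  res$pi_ratio <- sc$theta_pi / sw$theta_pi
  res$log_ratio <- log((sc$theta_pi + delta) / (sw$theta_pi + delta))
  res$d_cultivated <- sc$tajima_d
  def_ratio <- is.finite(res$log_ratio) & (sw$n_segregating +
                                             sc$n_segregating) > 0L
  def_d <- is.finite(res$d_cultivated)
  if (sum(def_ratio & def_d) < 50)
    stop("fewer than 50 windows with defined statistics; ",
         "Z standardization would be unreliable")
  res$z_ratio <- z_standardize(res$log_ratio, def_ratio)
  res$z_d <- z_standardize(res$d_cultivated, def_d)
  res$p_ratio <- stats::pnorm(res$z_ratio)
  res$p_d <- stats::pnorm(res$z_d)
  res$selected <- def_ratio & def_d &
    !is.na(res$p_ratio) & !is.na(res$p_d) &
    res$p_ratio < alpha & res$p_d < alpha
  attr(res, "alpha") <- alpha
  attr(res, "transition") <- "domestication"
  class(res) <- c("scan_result", "data.frame")
  res
}

# Genome-wide standardization with iterative sigma clipping: the mean and
# standard deviation are estimated on windows within `clip` SDs of the
# mean, re-estimated until the kept set stabilizes. True sweep windows are
# a small minority of extreme outliers; without clipping they inflate the
# scale estimate and mask themselves, while under a sweep-free genome the
# clip removes almost nothing and the estimates match the plain moments.
z_standardize <- function(x, defined, clip = 3, max_iter = 20) {
  z <- rep(NA_real_, length(x))
  keep <- defined
  mu <- NA_real_; sdev <- NA_real_
  for (it in seq_len(max_iter)) {
    mu <- mean(x[keep])
    sdev <- stats::sd(x[keep])
    if (is.na(sdev) || sdev == 0) return(z)
    keep2 <- defined & abs(x - mu) <= clip * sdev
    if (identical(keep2, keep)) break
    keep <- keep2
  }
  z[defined] <- (x[defined] - mu) / sdev
  z
}

#' PBS sweep scan for the improvement transition
#'
#' Per window: Fst for the three population pairs (elite-landrace,
#' elite-wild, landrace-wild), the log branch transform, and the elite
#' population branch statistic. PBS is standardized genome-wide, converted
#' to an upper-tail normal P, Bonferroni-corrected by the number of defined
#' windows, and a window is selected when the corrected P falls below
#' `alpha_corrected`.
#'
#' @inheritParams domestication_scan
#' @param alpha_corrected Bonferroni-corrected significance threshold
#'   (default 0.001).
#' @param estimator Fst estimator flag, see [window_fst()].
#' @return Data frame of class `pbs_result`: windows plus `fst_le`,
#'   `fst_ew`, `fst_lw`, `pbs_elite`, `z_pbs`, `p_raw`, `p_bonferroni`,
#'   `selected`.
#' @export
improvement_scan <- function(gm, manifest, windows, alpha_corrected = 0.001,
                             exclude = character(),
                             estimator = "hudson") {
  if (length(exclude)) {
    keep <- !(manifest$sample %in% exclude)
    manifest <- population_manifest(manifest$sample[keep],
                                    manifest$label[keep])
    gm_keep <- gm$samples %in% manifest$sample
    gm <- genotype_matrix(gm$calls[gm_keep, , drop = FALSE], gm$sites,
                          gm$samples[gm_keep])
  }
  validate_manifest(gm, manifest, require_three = TRUE)
  res <- windows
  res$fst_le <- window_fst(gm, windows, manifest, "elite", "landrace",
                           estimator = estimator)
  res$fst_ew <- window_fst(gm, windows, manifest, "elite", "wild",
                           estimator = estimator)
  res$fst_lw <- window_fst(gm, windows, manifest, "landrace", "wild",
                           estimator = estimator)
  res$pbs_elite <- pbs(res$fst_le, res$fst_ew, res$fst_lw)
  def <- is.finite(res$pbs_elite)
  if (sum(def) < 50)
    stop("fewer than 50 windows with defined PBS; ",
         "Z standardization would be unreliable")
  res$z_pbs <- z_standardize(res$pbs_elite, def)
  res$p_raw <- stats::pnorm(res$z_pbs, lower.tail = FALSE)
  n_def <- sum(def)
  res$p_bonferroni <- pmin(1, res$p_raw * n_def)
  res$selected <- def & !is.na(res$p_bonferroni) &
    res$p_bonferroni < alpha_corrected
  attr(res, "alpha_corrected") <- alpha_corrected
  attr(res, "n_tested") <- n_def
  attr(res, "transition") <- "improvement"
  class(res) <- c("pbs_result", "data.frame")
  res
}

#' Merge selected windows into sweep regions
#'
#' Overlapping or book-ended selected windows on the same chromosome are
#' merged into maximal regions (interval union).
#'
#' @param scan A `scan_result`/`pbs_result` data frame (or any window data
#'   frame with a logical `selected` column; a `p` column named `p_ratio`
#'   or `p_raw` supplies `min_p`).
#' @param transition Label stored on the output regions; taken from the
#'   scan attribute when present.
#' @return Data frame of class `sweep_regions`: `chrom`, `start`, `end`
#'   (0-based half-open), `transition`, `n_windows`, `min_p`, sorted and
#'   non-overlapping, with attribute `total_mb`.
#' @export
merge_windows <- function(scan, transition = attr(scan, "transition")) {
  if (is.null(transition)) transition <- "unspecified"
  sel <- scan[scan$selected %in% TRUE, , drop = FALSE]
  pcol <- intersect(c("p_ratio", "p_raw"), names(sel))[1]
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), transition = character(),
                      n_windows = integer(), min_p = numeric())
  if (!nrow(sel)) {
    attr(empty, "total_mb") <- 0
    class(empty) <- c("sweep_regions", "data.frame")
    return(empty)
  }
  out <- list()
  for (ch in sort(unique(sel$chrom))) {
    s <- sel[sel$chrom == ch, ]
    ir <- IRanges::IRanges(start = s$start + 1L, end = s$end)
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    n_win <- tabulate(S4Vectors::subjectHits(ov), length(red))
    min_p <- rep(NA_real_, length(red))
    if (!is.na(pcol)) {
      min_p <- vapply(seq_along(red), function(k) {
        members <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == k]
        min(s[[pcol]][members], na.rm = TRUE)
      }, numeric(1))
    }
    out[[ch]] <- data.frame(chrom = ch,
                            start = IRanges::start(red) - 1L,
                            end = IRanges::end(red),
                            transition = transition,
                            n_windows = n_win, min_p = min_p)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "total_mb") <- sum(res$end - res$start) / 1e6
  class(res) <- c("sweep_regions", "data.frame")
  res
}

#' Diversity-reduction summary across the two transitions
#'
#' Percentages relative to the wild baseline: diversity retained in
#' cultivars (`100 * pi_cultivated / pi_wild`), reduction during early
#' domestication (`100 * (pi_wild - pi_landrace) / pi_wild`) and further
#' reduction during improvement
#' (`100 * (pi_landrace - pi_elite) / pi_wild`). The two reductions
#' telescope to the total wild-to-elite loss.
#'
#' @param pi_wild,pi_landrace,pi_elite,pi_cultivated Genome-wide per-site
#'   theta-pi of each group (all `> 0`).
#' @return Named list `retention_pct`, `domestication_reduction_pct`,
#'   `improvement_reduction_pct`.
#' @export
diversity_reduction_summary <- function(pi_wild, pi_landrace, pi_elite,
                                        pi_cultivated) {
  vals <- c(pi_wild, pi_landrace, pi_elite, pi_cultivated)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all diversity inputs must be positive")
  list(
    retention_pct = unname(100 * pi_cultivated / pi_wild),
    domestication_reduction_pct =
      unname(100 * (pi_wild - pi_landrace) / pi_wild),
    improvement_reduction_pct =
      unname(100 * (pi_landrace - pi_elite) / pi_wild)
  )
}

#' Write a scan table as TSV (BED-style coordinates)
#' @param scan A scan result data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write sweep regions as BED (transition in the name column)
#' @param regions A `sweep_regions` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  d <- data.frame(regions$chrom, regions$start, regions$end,
                  regions$transition)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
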