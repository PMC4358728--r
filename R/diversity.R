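#' Sliding windows over a genome
#'
#' Default geometry is a 20 kb window advancing in 2 kb steps. Terminal
#' partial windows are dropped so that every window has the full span and
#' window statistics are comparable genome-wide; a chromosome shorter than
#' one window yields a single whole-chromosome window (logged via message).
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param window Window size in bp.
#' @param step Step size in bp; must satisfy `window >= step > 0`.
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
sliding_windows <- function(chrom_lengths, window = 20000, step = 2000) {
  if (step <= 0 || window < step)
    stop("need window >= step > 0")
  if (is.null(names(chrom_lengths)))
    stop("`chrom_lengths` must be named by chromosome")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    if (len < window) {
      message("chromosome ", ch, " (", len,
              " bp) shorter than one window; using whole chromosome")
      return(data.frame(chrom = ch, start = 0, end = len))
    }
    starts <- seq(0, len - window, by = step)
    data.frame(chrom = ch, start = starts, end = starts + window)
  })
  do.call(rbind, out)
}

# Harmonic sums and the Tajima (1989) normalizing constants for a haploid
# sample of size n.
tajima_constants <- function(n) {
  if (n < 2) stop("Tajima constants require haploid n >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

# Per-site unbiased heterozygosity contributions and segregation flags.
# pi_site = 2 * c * (n - c) / (n * (n - 1)) with n the site's own haploid
# sample size; sites with fewer than 2 alleles contribute nothing.
site_pi_components <- function(gm) {
  ac <- allele_count_table(gm)
  n <- ac$n_alleles
  cnt <- ac$alt_count
  usable <- n >= 2L
  pi <- numeric(length(n))
  pi[usable] <- 2 * cnt[usable] * (n[usable] - cnt[usable]) /
    (n[usable] * (n[usable] - 1))
  seg <- usable & cnt > 0L & cnt < n
  list(pi = pi, seg = seg, n = n, usable = usable)
}

#' Windowed diversity statistics
#'
#' Computes, for every window, per-site pairwise diversity (theta-pi), the
#' per-site Watterson estimator (theta-w), Tajima's D and the count of
#' segregating sites. Theta-pi sums each site's own unbiased heterozygosity
#' (so missing data enter through the site's own allele count); theta-w and
#' the D constants use the window's median haploid sample size. Per-site
#' denominators use the full window span by default; `denominator =
#' "callable"` divides by the number of genotyped variant sites instead
#' (per-variant-site diversity).
#'
#' @param gm A `genotype_matrix`.
#' @param windows Data frame from [sliding_windows()].
#' @param denominator `"span"` (window width, default) or `"callable"`.
#' @return `windows` extended with columns `n_segregating`, `theta_pi`,
#'   `theta_w`, `tajima_d`, `n_haploid` (median) and `pi_total` (window sum
#'   of per-site heterozygosity, the quantity entering D).
#' @export
window_diversity <- function(gm, windows,
                             denominator = c("span", "callable")) {
  denominator <- match.arg(denominator)
  comp <- site_pi_components(gm)
  pos <- gm$sites$pos
  chrom <- gm$sites$chrom
  res <- windows
  res$n_segregating <- 0L
  res$pi_total <- 0
  res$theta_pi <- 0
  res$theta_w <- NA_real_
  res$tajima_d <- NA_real_
  res$n_haploid <- NA_real_

  for (ch in unique(windows$chrom)) {
    on_ch <- which(chrom == ch)
    wi <- which(windows$chrom == ch)
    if (!length(wi)) next
    pp <- pos[on_ch]
    cpi <- c(0, cumsum(comp$pi[on_ch]))
    cseg <- c(0, cumsum(comp$seg[on_ch]))
    cuse <- c(0, cumsum(comp$usable[on_ch]))
    lo <- findInterval(windows$start[wi], pp) + 1L # first pos > start
    hi <- findInterval(windows$end[wi], pp)        # last pos <= end
    s_win <- as.integer(cseg[hi + 1L] - cseg[lo])
    pi_win <- cpi[hi + 1L] - cpi[lo]
    use_win <- cuse[hi + 1L] - cuse[lo]
    span <- if (denominator == "span") windows$end[wi] - windows$start[wi]
            else pmax(use_win, 1)
    n_med <- vapply(seq_along(wi), function(k) {
      if (hi[k] < lo[k]) return(NA_real_)
      nn <- comp$n[on_ch][lo[k]:hi[k]]
      nn <- nn[nn >= 2L]
      if (!length(nn)) NA_real_ else stats::median(nn)
    }, numeric(1))
    res$n_segregating[wi] <- s_win
    res$pi_total[wi] <- pi_win
    res$theta_pi[wi] <- pi_win / span
    def_w <- !is.na(n_med) & n_med >= 2
    a1 <- ifelse(def_w, vapply(ifelse(def_w, n_med, 2), function(nn)
      sum(1 / seq_len(max(round(nn), 2) - 1)), numeric(1)), NA_real_)
    res$theta_w[wi] <- ifelse(def_w, s_win / (a1 * span), NA_real_)
    res$n_haploid[wi] <- n_med
    dd <- rep(NA_real_, length(wi))
    for (k in which(def_w & s_win >= 1L & n_med >= 4)) {
      dd[k] <- tajima_d_from_totals(pi_win[k], s_win[k],
                                    as.integer(round(n_med[k])))
    }
    res$tajima_d[wi] <- dd
  }
  res
}

tajima_d_from_totals <- function(pi_total, s, n) {
  k <- tajima_constants(n)
  denom <- sqrt(k$e1 * s + k$e2 * s * (s - 1))
  if (denom == 0) return(NA_real_)
  (pi_total - s / k$a1) / denom
}

one_window_stats <- function(gm, window, denominator = "span") {
  stopifnot(all(c("chrom", "start", "end") %in% names(window)))
  window_diversity(gm, as.data.frame(window)[1, c("chrom", "start", "end")],
                   denominator = denominator)
}

#' Per-site pairwise nucleotide diversity in one window
#'
#' @param gm A `genotype_matrix`.
#' @param window One-row data frame (or list) with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param denominator See [window_diversity()].
#' @return Per-site theta-pi (0 when the window holds no genotyped sites).
#' @export
theta_pi <- function(gm, window, denominator = "span") {
  one_window_stats(gm, window, denominator)$theta_pi
}

#' Per-site Watterson estimator in one window
#' @inheritParams theta_pi
#' @return Per-site theta-w, or `NA` when no site has two genotyped alleles.
#' @export
theta_w <- function(gm, window, denominator = "span") {
  one_window_stats(gm, window, denominator)$theta_w
}

#' Tajima's D in one window
#'
#' `D = (pi_total - S/a1) / sqrt(e1 S + e2 S (S - 1))` on window totals,
#' with the Tajima (1989) constants evaluated at the window's median haploid
#' sample size. Undefined (NA) when the window has no segregating sites.
#'
#' @inheritParams theta_pi
#' @return Tajima's D or `NA`.
#' @export
tajimas_d <- function(gm, window) {
  one_window_stats(gm, window)$tajima_d
}

#' Genome-wide per-site diversity of a group
#'
#' Total per-site heterozygosity over all sites divided by total genome
#' length; the quantity summarized per population before computing
#' diversity-reduction percentages.
#'
#' @param gm A `genotype_matrix`.
#' @param genome_length Total genome length in bp.
#' @return Per-site theta-pi.
#' @export
genome_theta_pi <- function(gm, genome_length) {
  comp <- site_pi_components(gm)
  sum(comp$pi) / genome_length
}

#' SNV accumulation (rarefaction) curve
#'
#' For each subsample size `k`, the expected number of variant sites at
#' which at least one of `k` randomly chosen accessions carries the
#' alternate allele. At `k` equal to the group size the curve equals the
#' group's total SNV count with zero variance.
#'
#' @param gm A `genotype_matrix`.
#' @param manifest A `population_manifest`.
#' @param group Population label (see [population_samples()]).
#' @param k_values Integer vector of subsample sizes (each `<=` group size).
#' @param reps Monte-Carlo replicates per `k`.
#' @param seed Integer seed.
#' @param exhaustive Enumerate all subsets instead of sampling whenever
#'   `choose(n, k) <= max_subsets`.
#' @param max_subsets Cap for exhaustive enumeration.
#' @return Data frame `k`, `mean`, `sd`, `reps` (reps = number of subsets
#'   actually evaluated).
#' @export
snv_accumulation <- function(gm, manifest, group, k_values, reps = 100,
                             seed = 1, exhaustive = FALSE,
                             max_subsets = 10000) {
  sub <- subset_population(gm, manifest, group)
  n <- n_samples(sub)
  if (any(k_values > n))
    stop("k exceeds group size (", n, ")")
  if (any(k_values < 1)) stop("k must be >= 1")
  carrier <- sub$calls > 0L # sample x site
  set.seed(seed)
  rows <- lapply(k_values, function(k) {
    if (k == n) {
      tot <- sum(colSums(carrier) > 0L)
      return(data.frame(k = k, mean = tot, sd = 0, reps = 1L))
    }
    if (exhaustive && choose(n, k) <= max_subsets) {
      subsets <- utils::combn(n, k)
      counts <- apply(subsets, 2L, function(idx)
        sum(colSums(carrier[idx, , drop = FALSE]) > 0L))
    } else {
      counts <- vapply(seq_len(reps), function(r) {
        idx <- sample.int(n, k)
        sum(colSums(carrier[idx, , drop = FALSE]) > 0L)
      }, numeric(1))
    }
    data.frame(k = k, mean = mean(counts), sd = stats::sd(counts),
               reps = length(counts))
  })
  do.call(rbind, rows)
}

#' Site frequency spectrum
#'
#' Histogram of alternate-allele counts over a set of sites, treating the
#' reference allele as ancestral. The folded variant bins by minor-allele
#' count instead.
#'
#' @param gm A `genotype_matrix` (typically a single population).
#' @param site_subset Optional integer/logical index of sites; default all.
#' @param folded Fold the spectrum at the minor allele.
#' @param min_n Minimum haploid sample size for a site to enter the
#'   spectrum.
#' @return Data frame `count` (derived-allele count), `n_sites`. The sum of
#'   `n_sites` equals the number of subset sites passing `min_n`.
#' @export
sfs <- function(gm, site_subset = NULL, folded = FALSE, min_n = 2) {
  ac <- allele_count_table(gm)
  idx <- if (is.null(site_subset)) seq_len(n_sites(gm))
         else seq_len(n_sites(gm))[site_subset]
  n <- ac$n_alleles[idx]
  cnt <- ac$alt_count[idx]
  keep <- n >= min_n
  n <- n[keep]; cnt <- cnt[keep]
  if (!length(cnt))
    return(data.frame(count = integer(), n_sites = integer()))
  if (folded) cnt <- pmin(cnt, n - cnt)
  top <- max(n)
  tab <- tabulate(cnt + 1L, nbins = top + 1L)
  data.frame(count = 0:top, n_sites = tab)
}
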