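#' Configuration for the three-population simulator
#'
#' The generator emulates a wild -> landrace -> elite breeding history:
#' neutral standing variation in the wild population, two nested founder
#' bottlenecks that trim diversity to configurable retention fractions, and
#' optional selective sweeps in which a beneficial allele is driven to
#' fixation in the selected population(s) with a linear collapse of
#' flanking heterozygosity.
#'
#' Defaults mirror the study system the package targets: 31 wild, 15
#' landrace and 24 elite soybean accessions; wild per-site diversity
#' `theta = 3.84e-3`; landrace/wild retention `0.625` and elite/landrace
#' retention `0.867` (the ratios of the observed group diversities
#' 2.40e-3/3.84e-3 and 2.08e-3/2.40e-3).
#'
#' @param n_wild,n_landrace,n_elite Diploid sample counts per population.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param theta Scaled per-site mutation parameter; the wild sample's
#'   expected per-site pairwise diversity.
#' @param bottleneck_domestication Diversity retention fraction
#'   landrace/wild, in (0, 1].
#' @param bottleneck_improvement Diversity retention fraction
#'   elite/landrace, in (0, 1].
#' @param sweep_specs `NULL` or a data frame with columns `chrom`, `start`,
#'   `end` (0-based half-open) and `transition`
#'   (`"domestication"`/`"improvement"`); intervals must lie within the
#'   chromosome and not overlap.
#' @param mean_depth Mean sequencing depth of the Poisson read model.
#' @param error_rate Per-read base error rate of the binomial read model.
#' @param emit_likelihoods Simulate per-genotype read likelihoods (the
#'   memory-heavy part of the output; disable when only genotypes are
#'   needed).
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_wild = 31, n_landrace = 15, n_elite = 24,
                       n_chrom = 1, chrom_length = 2e6, theta = 3.84e-3,
                       bottleneck_domestication = 0.625,
                       bottleneck_improvement = 0.867,
                       sweep_specs = NULL, mean_depth = 10,
                       error_rate = 0.01, emit_likelihoods = TRUE,
                       seed = 1) {
  cfg <- list(n_wild = as.integer(n_wild),
              n_landrace = as.integer(n_landrace),
              n_elite = as.integer(n_elite),
              n_chrom = as.integer(n_chrom),
              chrom_length = as.integer(chrom_length), theta = theta,
              bottleneck_domestication = bottleneck_domestication,
              bottleneck_improvement = bottleneck_improvement,
              sweep_specs = sweep_specs, mean_depth = mean_depth,
              error_rate = error_rate,
              emit_likelihoods = isTRUE(emit_likelihoods),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$bottleneck_domestication <= 0 || cfg$bottleneck_domestication > 1 ||
      cfg$bottleneck_improvement <= 0 || cfg$bottleneck_improvement > 1)
    stop("retention fractions must lie in (0, 1]")
  if (min(cfg$n_wild, cfg$n_landrace, cfg$n_elite) < 1)
    stop("all three populations need at least one sample")
  sw <- cfg$sweep_specs
  if (!is.null(sw) && nrow(sw)) {
    stopifnot(all(c("chrom", "start", "end", "transition") %in% names(sw)))
    if (!all(sw$transition %in% c("domestication", "improvement")))
      stop("sweep transition must be 'domestication' or 'improvement'")
    if (any(sw$start < 0 | sw$end > cfg$chrom_length | sw$start >= sw$end))
      stop("sweep intervals must lie within [0, chrom_length)")
    if (!all(sw$chrom %in% sim_chrom_names(cfg)))
      stop("sweep chrom not in simulated genome")
    for (ch in unique(sw$chrom)) {
      s <- sw[sw$chrom == ch, ]
      s <- s[order(s$start), ]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
        stop("sweep intervals on one chromosome must not overlap")
    }
  }
  invisible(TRUE)
}

sim_chrom_names <- function(cfg) sprintf("chr%d", seq_len(cfg$n_chrom))

# Founder-bottleneck frequency resampling. A founder pool of k haploid
# lineages retains a fraction (1 - 1/k) of heterozygosity in expectation;
# mixing pool sizes k and k+1 per site interpolates to any retention in
# (0, 1].
bottleneck_freq <- function(p, retention) {
  if (retention >= 1) return(p)
  k <- floor(1 / (1 - retention))
  w <- (retention - (1 - 1 / k)) * k * (k + 1)
  w <- min(max(w, 0), 1)
  ks <- k + stats::rbinom(length(p), 1L, w)
  stats::rbinom(length(p), ks, p) / ks
}

# Heterozygosity collapse for sweep escapees: scale a site's
# heterozygosity by f in [0,1], moving the frequency toward the swept
# (high) side. Monomorphic sites are left untouched.
ramp_to_fixation <- function(p, f) {
  h_old <- 2 * p * (1 - p)
  h_new <- pmin(f * h_old, 0.5)
  out <- (1 + sqrt(pmax(1 - 2 * h_new, 0))) / 2
  ifelse(h_old == 0, p, out)
}

# Hard-sweep transform of population frequencies inside one sweep
# interval: a site hitchhikes to fixation for the allele carried by the
# beneficial haplotype with probability 1 - sqrt(f) (f = relative distance
# from the focal site), otherwise it escapes by recombination and keeps a
# partially ramped frequency. Expected heterozygosity follows the linear
# ramp f * h. `escaped` and `hitch_allele` are drawn once per site so that
# populations sharing the sweep (landrace and elite in a domestication
# sweep) inherit the same haplotype outcome.
sweep_transform <- function(p, f, escaped, hitch_allele) {
  ifelse(escaped, ramp_to_fixation(p, sqrt(f)), hitch_allele)
}

#' Simulate a three-population genotype data set with known truth
#'
#' Wild derived-allele frequencies are drawn from the standing neutral
#' spectrum (P(count = i) proportional to 1/i over the wild haploid sample);
#' landrace frequencies are resampled from wild through a binomial founder
#' bottleneck sized to the configured retention, and elite likewise from
#' landrace. Inside each sweep the beneficial allele is forced to frequency
#' 1 in the selected population(s) (domestication: landrace and elite;
#' improvement: elite only) and flanking heterozygosity decays linearly to
#' zero at the focal site. Genotypes are drawn under Hardy-Weinberg within
#' population; likelihoods come from a Poisson-depth binomial read model.
#'
#' @param cfg A `sim_config`.
#' @return List of class `sweep_sim` with elements `genotypes`
#'   (`genotype_matrix` of the true genotypes), `likelihoods`
#'   (`genotype_likelihoods`), `manifest` (`population_manifest`) and
#'   `truth` (list with `swept_regions` and `fixed_loci` data frames).
#' @export
simulate_populations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  nt <- c("A", "C", "G", "T")
  n_hap_w <- 2L * cfg$n_wild
  a1_w <- sum(1 / seq_len(n_hap_w - 1L))
  chroms <- sim_chrom_names(cfg)
  sw <- cfg$sweep_specs
  if (is.null(sw)) sw <- data.frame(chrom = character(), start = integer(),
                                    end = integer(),
                                    transition = character())

  site_list <- list()
  for (ch in chroms) {
    s_count <- stats::rpois(1L, cfg$theta * a1_w * cfg$chrom_length)
    s_count <- min(s_count, cfg$chrom_length)
    pos <- sort(sample.int(cfg$chrom_length, s_count))
    # derived count i with probability proportional to 1/i
    i <- sample.int(n_hap_w - 1L, s_count, replace = TRUE,
                    prob = 1 / seq_len(n_hap_w - 1L))
    p_w <- i / n_hap_w
    # guarantee a segregating focal site at each sweep midpoint
    swc <- sw[sw$chrom == ch, , drop = FALSE]
    focal <- integer(0)
    if (nrow(swc)) {
      mid <- as.integer(floor((swc$start + swc$end) / 2)) + 1L
      for (j in seq_along(mid)) {
        hit <- match(mid[j], pos)
        if (is.na(hit)) {
          pos <- c(pos, mid[j])
          p_w <- c(p_w, 0)
        } else {
          p_w[hit] <- 0
        }
      }
      ord <- order(pos)
      pos <- pos[ord]; p_w <- p_w[ord]
      focal <- match(mid, pos)
      p_w[focal] <- stats::runif(length(focal), 0.3, 0.7)
    }
    site_list[[ch]] <- data.frame(chrom = ch, pos = pos, p_w = p_w,
                                  focal = seq_along(pos) %in% focal,
                                  stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_list)
  rownames(sites) <- NULL
  s_tot <- nrow(sites)

  p_l <- bottleneck_freq(sites$p_w, cfg$bottleneck_domestication)
  p_e <- bottleneck_freq(p_l, cfg$bottleneck_improvement)
  # keep sweep focal sites polymorphic upstream of the selected transition
  foc <- which(sites$focal)
  if (length(foc)) {
    p_l[foc] <- sites$p_w[foc]
    p_e[foc] <- p_l[foc]
  }

  # sweep injection: per population, per site frequency transform
  fixed_truth <- list()
  for (j in seq_len(nrow(sw))) {
    ch <- sw$chrom[j]; st <- sw$start[j]; en <- sw$end[j]
    mid <- floor((st + en) / 2) + 1L
    in_sw <- which(sites$chrom == ch & sites$pos > st & sites$pos <= en)
    f <- pmin(abs(sites$pos[in_sw] - mid) / ((en - st) / 2), 1)
    escaped <- stats::runif(length(in_sw)) < sqrt(f)
    if (sw$transition[j] == "domestication") {
      hitch <- as.numeric(stats::runif(length(in_sw)) < p_l[in_sw])
      hitch[f == 0] <- 1 # the focal beneficial allele is the alternate
      p_l[in_sw] <- sweep_transform(p_l[in_sw], f, escaped, hitch)
      p_e[in_sw] <- sweep_transform(p_e[in_sw], f, escaped, hitch)
      fixed_pop <- "cultivated"
    } else {
      hitch <- as.numeric(stats::runif(length(in_sw)) < p_e[in_sw])
      hitch[f == 0] <- 1
      p_e[in_sw] <- sweep_transform(p_e[in_sw], f, escaped, hitch)
      fixed_pop <- "elite"
    }
    fixed_truth[[j]] <- data.frame(chrom = ch, pos = mid,
                                   fixed_population = fixed_pop,
                                   stringsAsFactors = FALSE)
  }

  draw_pop <- function(n, p) {
    matrix(stats::rbinom(n * s_tot, 2L, rep(p, each = n)), nrow = n)
  }
  calls <- rbind(draw_pop(cfg$n_wild, sites$p_w),
                 draw_pop(cfg$n_landrace, p_l),
                 draw_pop(cfg$n_elite, p_e))
  samples <- c(sprintf("W%02d", seq_len(cfg$n_wild)),
               sprintf("L%02d", seq_len(cfg$n_landrace)),
               sprintf("E%02d", seq_len(cfg$n_elite)))
  labels <- rep(c("wild", "landrace", "elite"),
                c(cfg$n_wild, cfg$n_landrace, cfg$n_elite))
  manifest <- population_manifest(samples, labels)

  # fixation truth needs the comparison group polymorphic in the realized
  # genotypes; nudge one sample to a heterozygote if sampling collapsed it
  if (length(foc)) {
    wild_rows <- which(labels == "wild")
    land_rows <- which(labels == "landrace")
    for (j in seq_len(nrow(sw))) {
      col <- foc[j]
      other_rows <- if (sw$transition[j] == "domestication") wild_rows
                    else land_rows
      if (length(unique(calls[other_rows, col])) < 2L)
        calls[other_rows[1L], col] <- 1L
    }
  }

  # drop sites carrying no alternate allele in any sample (not observable
  # as SNVs against the reference)
  keep <- colSums(calls) > 0L
  keep[foc] <- TRUE
  calls <- calls[, keep, drop = FALSE]
  sites <- sites[keep, , drop = FALSE]

  ref <- sample(nt, nrow(sites), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), character(1))
  site_tab <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = ref,
                         alt = alt, id = NA_character_,
                         stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, site_tab, samples)

  gl <- if (cfg$emit_likelihoods)
    simulate_read_likelihoods(gm, cfg$mean_depth, cfg$error_rate)
  else NULL

  truth <- list(
    swept_regions = sw,
    fixed_loci = if (length(fixed_truth)) do.call(rbind, fixed_truth)
                 else data.frame(chrom = character(), pos = integer(),
                                 fixed_population = character())
  )
  structure(list(genotypes = gm, likelihoods = gl, manifest = manifest,
                 truth = truth, config = cfg),
            class = "sweep_sim")
}

# Poisson depth + binomial alternate-read model; returns per-genotype
# binomial likelihoods of the observed read configuration.
simulate_read_likelihoods <- function(gm, mean_depth, error_rate) {
  n <- n_samples(gm); s <- n_sites(gm)
  depth <- matrix(stats::rpois(n * s, mean_depth), n, s)
  p_alt_given_g <- c(error_rate, 0.5, 1 - error_rate)
  p_true <- matrix(p_alt_given_g[gm$calls + 1L], n, s)
  alt_reads <- matrix(stats::rbinom(n * s, as.vector(depth),
                                    as.vector(p_true)), n, s)
  lik <- array(0, c(n, s, 3L))
  for (g in 0:2)
    lik[, , g + 1L] <- matrix(stats::dbinom(as.vector(alt_reads),
                                            as.vector(depth),
                                            p_alt_given_g[g + 1L]), n, s)
  genotype_likelihoods(lik, gm$sites, gm$samples)
}

#' Write the full fixture file set for a simulated data set
#'
#' Produces every input the downstream pipeline reads: a VCF (GT + GL), a
#' population manifest TSV, a truth TSV (swept regions and fixed loci), a
#' toy genome FASTA consistent with the reference alleles, a GFF3 with CDS
#' gene models placed over the sweeps (plus background genes), a QTL BED
#' and a gene-to-category TSV.
#'
#' @param sim A `sweep_sim` from [simulate_populations()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the seven file paths, invisibly.
#' @export
write_fixtures <- function(sim, dir) {
  stopifnot(inherits(sim, "sweep_sim"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  cfg <- sim$config
  paths <- c(vcf = file.path(dir, "sim.vcf"),
             manifest = file.path(dir, "manifest.tsv"),
             truth = file.path(dir, "truth.tsv"),
             fasta = file.path(dir, "genome.fasta"),
             gff3 = file.path(dir, "genes.gff3"),
             qtl = file.path(dir, "qtl.bed"),
             categories = file.path(dir, "gene_categories.tsv"))
  write_vcf(sim$genotypes, paths["vcf"], gl = sim$likelihoods)
  write_manifest(sim$manifest, paths["manifest"])

  tr <- sim$truth
  truth_rows <- rbind(
    if (nrow(tr$swept_regions))
      data.frame(record = "sweep", chrom = tr$swept_regions$chrom,
                 start = tr$swept_regions$start, end = tr$swept_regions$end,
                 detail = tr$swept_regions$transition),
    if (nrow(tr$fixed_loci))
      data.frame(record = "fixation", chrom = tr$fixed_loci$chrom,
                 start = tr$fixed_loci$pos - 1L, end = tr$fixed_loci$pos,
                 detail = tr$fixed_loci$fixed_population)
  )
  if (is.null(truth_rows))
    truth_rows <- data.frame(record = character(), chrom = character(),
                             start = integer(), end = integer(),
                             detail = character())
  utils::write.table(truth_rows, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # genome consistent with the reference alleles at every variant site
  set.seed(cfg$seed + 1L)
  seqs <- lapply(sim_chrom_names(cfg), function(ch) {
    s <- sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE)
    on_ch <- sim$genotypes$sites$chrom == ch
    s[sim$genotypes$sites$pos[on_ch]] <- sim$genotypes$sites$ref[on_ch]
    paste(s, collapse = "")
  })
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- sim_chrom_names(cfg)
  Biostrings::writeXStringSet(genome, paths["fasta"])

  gene_tab <- toy_gene_models(sim)
  write_gff3(gene_tab, paths["gff3"])

  qtl <- toy_qtls(sim)
  utils::write.table(
    data.frame(qtl$chrom, qtl$start, qtl$end, qtl$trait),
    paths["qtl"], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)

  cats <- toy_gene_categories(gene_tab, sim)
  utils::write.table(cats, paths["categories"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

# One 2-exon gene per sweep (centred on the focal site) plus background
# genes spaced along each chromosome. Coordinates 1-based inclusive (GFF3).
toy_gene_models <- function(sim) {
  cfg <- sim$config
  sw <- sim$truth$swept_regions
  rows <- list()
  gid <- 0L
  add_gene <- function(ch, start, strand, tag) {
    gid <<- gid + 1L
    # two CDS segments of 300 bp separated by a 100 bp intron
    data.frame(gene_id = sprintf("gene%03d", gid),
               transcript_id = sprintf("gene%03d.t1", gid),
               chrom = ch, strand = strand,
               start = c(start, start + 400L),
               end = c(start + 299L, start + 699L),
               phase = c(0L, 0L), tag = tag, stringsAsFactors = FALSE)
  }
  for (j in seq_len(nrow(sw))) {
    mid <- floor((sw$start[j] + sw$end[j]) / 2) + 1L
    strand <- if (j %% 2L == 0L) "-" else "+"
    rows[[length(rows) + 1L]] <-
      add_gene(sw$chrom[j], max(1L, mid - 350L), strand, "swept")
  }
  for (ch in sim_chrom_names(cfg)) {
    starts <- seq(5000L, cfg$chrom_length - 1000L,
                  length.out = min(10L, max(2L, cfg$chrom_length %/% 20000L)))
    for (st in as.integer(starts))
      rows[[length(rows) + 1L]] <- add_gene(ch, st, "+", "background")
  }
  do.call(rbind, rows)
}

write_gff3 <- function(gene_tab, path) {
  lines <- "##gff-version 3"
  for (g in unique(gene_tab$gene_id)) {
    seg <- gene_tab[gene_tab$gene_id == g, ]
    lines <- c(lines,
      paste(seg$chrom[1], "divsweep", "gene", min(seg$start), max(seg$end),
            ".", seg$strand[1], ".", sprintf("ID=%s", g), sep = "\t"),
      paste(seg$chrom[1], "divsweep", "mRNA", min(seg$start), max(seg$end),
            ".", seg$strand[1], ".",
            sprintf("ID=%s;Parent=%s", seg$transcript_id[1], g), sep = "\t"),
      paste(seg$chrom, "divsweep", "CDS", seg$start, seg$end, ".",
            seg$strand, seg$phase,
            sprintf("ID=cds.%s;Parent=%s", seg$transcript_id,
                    seg$transcript_id), sep = "\t"))
  }
  writeLines(lines, path)
}

toy_qtls <- function(sim) {
  cfg <- sim$config
  sw <- sim$truth$swept_regions
  traits <- c("seed_size", "shattering", "growth_habit", "oil_content",
              "flowering_time")
  if (nrow(sw)) {
    data.frame(chrom = sw$chrom,
               start = pmax(0L, sw$start - 50000L),
               end = pmin(cfg$chrom_length, sw$end + 50000L),
               trait = traits[(seq_len(nrow(sw)) - 1L) %% length(traits) + 1L],
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = sim_chrom_names(cfg)[1],
               start = 0L, end = min(100000L, cfg$chrom_length),
               trait = traits[1], stringsAsFactors = FALSE)
  }
}

toy_gene_categories <- function(gene_tab, sim) {
  genes <- unique(gene_tab[, c("gene_id", "tag")])
  cat <- ifelse(genes$tag == "swept", "transcription_factor",
                rep(c("metabolism", "disease_resistance", "transport"),
                    length.out = nrow(genes)))
  data.frame(gene = genes$gene_id, category = cat, stringsAsFactors = FALSE)
}
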