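# Shared fixture builders for the test suite. Everything is constructed in
# code; no data files.

# Genotype matrix from a calls matrix (samples x sites) on one chromosome.
make_gm <- function(calls, chrom = "chr1", pos = NULL,
                    samples = NULL) {
  calls <- as.matrix(calls)
  s <- ncol(calls)
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = s)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nrow(calls)))
  ref <- rep(c("A", "C", "G", "T"), length.out = s)
  alt <- rep(c("G", "T", "A", "C"), length.out = s)
  genotype_matrix(calls, data.frame(chrom = chrom, pos = pos, ref = ref,
                                    alt = alt), samples)
}

# Random genotype matrix with given dimensions and missing rate.
random_gm <- function(n = 10, s = 50, miss = 0, seed = 1) {
  set.seed(seed)
  calls <- matrix(sample(0:2, n * s, replace = TRUE), n, s)
  if (miss > 0) calls[runif(n * s) < miss] <- -1L
  make_gm(calls)
}

# Manifest covering a genotype matrix: first n_w samples wild, next n_l
# landrace, rest elite.
make_manifest <- function(gm, n_w, n_l) {
  n <- n_samples(gm)
  population_manifest(gm$samples,
                      rep(c("wild", "landrace", "elite"),
                          c(n_w, n_l, n - n_w - n_l)))
}

# Small fast simulation config for tests.
test_sim_config <- function(..., chrom_length = 3e5,
                            emit_likelihoods = FALSE, seed = 1) {
  sim_config(chrom_length = chrom_length,
             emit_likelihoods = emit_likelihoods, seed = seed, ...)
}

# One-row window data frame.
win <- function(chrom, start, end) data.frame(chrom = chrom, start = start,
                                              end = end)

# Brute-force per-site pairwise diversity: expand every sample into two
# alleles and average differences over all haplotype pairs. Independent of
# the package's frequency-based computation.
brute_theta_pi <- function(gm, window, span = NULL) {
  sel <- gm$sites$chrom == window$chrom & gm$sites$pos > window$start &
    gm$sites$pos <= window$end
  if (is.null(span)) span <- window$end - window$start
  total <- 0
  for (j in which(sel)) {
    cc <- gm$calls[, j]
    cc <- cc[cc >= 0]
    alleles <- unlist(lapply(cc, function(g) switch(as.character(g),
                                                    "0" = c(0, 0),
                                                    "1" = c(0, 1),
                                                    "2" = c(1, 1))))
    n <- length(alleles)
    if (n < 2) next
    diffs <- 0; pairs <- 0
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        diffs <- diffs + (alleles[a] != alleles[b])
        pairs <- pairs + 1
      }
    }
    total <- total + diffs / pairs
  }
  as.numeric(total) / span
}
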