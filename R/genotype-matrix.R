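#' Construct a multi-sample genotype matrix of biallelic SNVs
#'
#' The central container of the package: an integer matrix of diploid
#' genotype codes (rows = samples, columns = variant sites) together with
#' the site table. Codes are `0` (homozygous reference), `1` (heterozygous),
#' `2` (homozygous alternate) and `-1` (missing).
#'
#' @param calls Integer matrix, `n_samples x n_sites`, codes in
#'   `{-1, 0, 1, 2}`.
#' @param sites Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (single nucleotides) and optionally `id`. Sites must be sorted by
#'   `(chrom, pos)` and biallelic (`ref != alt`).
#' @param samples Character vector of sample identifiers, one per row of
#'   `calls`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `sites`, `samples`.
#' @export
genotype_matrix <- function(calls, sites, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(sites$id)) sites$id <- NA_character_
  sites <- data.frame(
    chrom = as.character(sites$chrom),
    pos = as.integer(sites$pos),
    ref = as.character(sites$ref),
    alt = as.character(sites$alt),
    id = as.character(sites$id),
    stringsAsFactors = FALSE
  )
  samples <- as.character(samples)
  if (nrow(calls) != length(samples))
    stop("`calls` must have one row per sample")
  if (ncol(calls) != nrow(sites))
    stop("`calls` must have one column per site")
  if (!all(calls %in% c(-1L, 0L, 1L, 2L)))
    stop("genotype codes must be in {-1, 0, 1, 2}")
  nt <- c("A", "C", "G", "T")
  if (!all(sites$ref %in% nt) || !all(sites$alt %in% nt))
    stop("ref and alt alleles must be single nucleotides in {A,C,G,T}")
  if (any(sites$ref == sites$alt))
    stop("sites must be biallelic: ref != alt")
  if (any(sites$pos < 1L))
    stop("positions are 1-based and must be >= 1")
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites))))
    stop("sites must be sorted by (chrom, pos)")
  rownames(calls) <- samples
  structure(list(calls = calls, sites = sites, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d biallelic SNV sites (%d chromosome(s))\n",
              n_samples(x), n_sites(x), length(unique(x$sites$chrom))))
  miss <- mean(x$calls == -1L)
  cat(sprintf("  missing call fraction: %.4f\n", miss))
  invisible(x)
}

#' Number of sites in a genotype matrix
#' @param gm A `genotype_matrix`.
#' @return Integer count.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' Number of samples in a genotype matrix
#' @param gm A `genotype_matrix`.
#' @return Integer count.
#' @export
n_samples <- function(gm) length(gm$samples)

#' Subset a genotype matrix by site index
#'
#' @param gm A `genotype_matrix`.
#' @param idx Integer or logical index into the site columns.
#' @return A `genotype_matrix` restricted to the selected sites (order is
#'   re-sorted by coordinate if the index permutes it).
#' @export
subset_sites <- function(gm, idx) {
  calls <- gm$calls[, idx, drop = FALSE]
  sites <- gm$sites[idx, , drop = FALSE]
  ord <- order(sites$chrom, sites$pos)
  genotype_matrix(calls[, ord, drop = FALSE], sites[ord, , drop = FALSE],
                  gm$samples)
}

#' Population manifest: sample-to-population labels
#'
#' Maps each sample to one of the labels `wild`, `landrace` or `elite`.
#' The derived group `cultivated` is the union of `landrace` and `elite`.
#'
#' @param samples Character vector of sample ids.
#' @param labels Character vector of the same length with values in
#'   `{wild, landrace, elite}`.
#' @return A data frame of class `population_manifest` with columns
#'   `sample` and `label`.
#' @export
population_manifest <- function(samples, labels) {
  samples <- as.character(samples)
  labels <- as.character(labels)
  if (length(samples) != length(labels))
    stop("`samples` and `labels` must have equal length")
  if (anyDuplicated(samples))
    stop("each sample must be labelled exactly once")
  bad <- setdiff(unique(labels), c("wild", "landrace", "elite"))
  if (length(bad))
    stop("unknown population label(s): ", paste(bad, collapse = ", "))
  structure(data.frame(sample = samples, label = labels,
                       stringsAsFactors = FALSE),
            class = c("population_manifest", "data.frame"))
}

#' Samples belonging to a population label
#'
#' @param manifest A `population_manifest`.
#' @param label One of `"wild"`, `"landrace"`, `"elite"`, the derived group
#'   `"cultivated"` (landrace plus elite) or `"all"`.
#' @return Character vector of sample ids.
#' @export
population_samples <- function(manifest, label) {
  label <- match.arg(label, c("wild", "landrace", "elite", "cultivated", "all"))
  if (label == "all") return(manifest$sample)
  keep <- if (label == "cultivated")
    manifest$label %in% c("landrace", "elite")
  else manifest$label == label
  manifest$sample[keep]
}

#' Restrict a genotype matrix to one population
#'
#' Sample order of the original matrix is preserved; sites are unchanged.
#'
#' @param gm A `genotype_matrix`.
#' @param manifest A `population_manifest` covering the matrix samples.
#' @param label Population label (see [population_samples()]).
#' @return A `genotype_matrix` holding only the requested samples.
#' @export
subset_population <- function(gm, manifest, label) {
  ids <- population_samples(manifest, label)
  keep <- gm$samples %in% ids
  if (!any(keep))
    stop("population '", label, "' has no samples in the genotype matrix")
  genotype_matrix(gm$calls[keep, , drop = FALSE], gm$sites,
                  gm$samples[keep])
}

#' Allele counts at one site
#'
#' Diploid samples contribute two alleles each; missing calls contribute
#' none. `alt_count` is the number of alternate alleles among the
#' non-missing calls, so `alt_count + ref_count = n_alleles` always.
#'
#' @param gm A `genotype_matrix`.
#' @param site_index Column index of the site.
#' @return Named integer vector `c(n_alleles = ..., alt_count = ...)`.
#' @export
allele_counts <- function(gm, site_index) {
  if (site_index < 1L || site_index > n_sites(gm))
    stop("site_index out of range")
  cc <- gm$calls[, site_index]
  ok <- cc >= 0L
  c(n_alleles = 2L * sum(ok), alt_count = sum(cc[ok]))
}

# Vectorized allele counts over all sites: list(n_alleles, alt_count),
# each an integer vector of length n_sites. Backbone of every window
# statistic.
allele_count_table <- function(gm) {
  ok <- gm$calls >= 0L
  n_alleles <- 2L * colSums(ok)
  calls0 <- gm$calls
  calls0[!ok] <- 0L
  list(n_alleles = as.integer(n_alleles),
       alt_count = as.integer(colSums(calls0)))
}

#' Maximum-likelihood consensus genotypes
#'
#' Allocates to every sample, at every site, the genotype with the highest
#' likelihood, producing the consensus matrix used for nucleotide-fixation
#' calling. Ties are broken toward the lowest genotype code and counted;
#' entries whose three likelihoods are all zero (or non-finite) are set to
#' missing and counted.
#'
#' @param gl A `genotype_likelihoods` object (see [genotype_likelihoods()]).
#' @return A `genotype_matrix` with attributes `n_ties` (tied argmax
#'   entries) and `n_flagged` (all-zero entries set to missing).
#' @export
assign_ml_genotypes <- function(gl) {
  stopifnot(inherits(gl, "genotype_likelihoods"))
  lik <- gl$lik # n_samples x n_sites x 3
  if (any(!is.finite(lik)))
    stop("all likelihoods must be finite")
  n <- dim(lik)[1L]
  s <- dim(lik)[2L]
  l0 <- lik[, , 1L, drop = FALSE]; dim(l0) <- c(n, s)
  l1 <- lik[, , 2L, drop = FALSE]; dim(l1) <- c(n, s)
  l2 <- lik[, , 3L, drop = FALSE]; dim(l2) <- c(n, s)
  best <- pmax(l0, l1, l2)
  # argmax with ties toward the lowest code
  calls <- matrix(2L, n, s)
  calls[l1 >= best] <- 1L
  calls[l0 >= best] <- 0L
  zero <- best <= 0
  n_ties <- sum(((l0 == best) + (l1 == best) + (l2 == best) > 1L) & !zero)
  calls[zero] <- -1L
  gm <- genotype_matrix(calls, gl$sites, gl$samples)
  attr(gm, "n_ties") <- n_ties
  attr(gm, "n_flagged") <- sum(zero)
  gm
}

#' Genotype likelihoods container
#'
#' Per sample and site, three non-negative likelihood values for the
#' genotypes (hom-ref, het, hom-alt). Likelihoods need not be normalized.
#'
#' @param lik Numeric array `n_samples x n_sites x 3` of non-negative
#'   values.
#' @param sites Site table as for [genotype_matrix()].
#' @param samples Sample ids.
#' @return An object of class `genotype_likelihoods`.
#' @export
genotype_likelihoods <- function(lik, sites, samples) {
  stopifnot(length(dim(lik)) == 3L, dim(lik)[3L] == 3L)
  if (dim(lik)[1L] != length(samples) || dim(lik)[2L] != nrow(sites))
    stop("likelihood array shape must be n_samples x n_sites x 3")
  if (any(lik < 0, na.rm = TRUE))
    stop("likelihoods must be non-negative")
  structure(list(lik = lik, sites = sites, samples = as.character(samples)),
            class = "genotype_likelihoods")
}
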