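#' PCA of a genotype matrix
#'
#' Sites are centered by their mean genotype and scaled by
#' `sqrt(p (1 - p))` where `p` is the sample alternate-allele frequency
#' (the normalization standard for genotype PCA); missing calls are
#' mean-imputed and monomorphic sites dropped. Coordinates come from the
#' singular value decomposition of the normalized matrix; components are
#' ordered by decreasing explained variance.
#'
#' @param gm A `genotype_matrix` with at least 2 samples and 2 polymorphic
#'   sites.
#' @param n_components Number of components to return.
#' @param scaling `"patterson"` (default) or `"center"` (no variance
#'   scaling).
#' @return List of class `genotype_pca`: `coords` (samples x components),
#'   `explained_variance` (fractions), `sdev`.
#' @export
pca_genotypes <- function(gm, n_components = 10,
                          scaling = c("patterson", "center")) {
  scaling <- match.arg(scaling)
  if (n_samples(gm) < 2) stop("PCA needs at least 2 samples")
  x <- gm$calls * 1.0
  x[x < 0] <- NA
  mu <- colMeans(x, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in which(colSums(is.na(x)) > 0L)) x[is.na(x[, j]), j] <- mu[j]
  p <- mu / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2) stop("need at least 2 polymorphic sites for PCA")
  x <- sweep(x[, poly, drop = FALSE], 2L, mu[poly])
  if (scaling == "patterson")
    x <- sweep(x, 2L, sqrt(p[poly] * (1 - p[poly])), "/")
  sv <- svd(x)
  k <- min(n_components, length(sv$d))
  coords <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                      k, k)
  rownames(coords) <- gm$samples
  colnames(coords) <- sprintf("PC%d", seq_len(k))
  structure(list(coords = coords,
                 explained_variance = sv$d^2 / sum(sv$d^2),
                 sdev = sv$d / sqrt(max(nrow(x) - 1, 1))),
            class = "genotype_pca")
}

#' Pairwise genetic distances between samples
#'
#' Allele-sharing distance (default): the mean over co-genotyped sites of
#' `|code_i - code_j| / 2`, i.e. half the Manhattan distance on genotype
#' codes — 0 for identical samples and 1 for opposite homozygotes at every
#' site. `"mismatch"` uses the raw proportion of differing genotype codes.
#'
#' @param gm A `genotype_matrix`.
#' @param method `"allele_sharing"` or `"mismatch"`.
#' @return Symmetric numeric matrix of class `dist_matrix` with zero
#'   diagonal, sample ids as dimnames.
#' @export
pairwise_distance <- function(gm, method = c("allele_sharing", "mismatch")) {
  method <- match.arg(method)
  n <- n_samples(gm)
  if (n < 2) stop("need at least 2 samples")
  calls <- gm$calls
  has_missing <- any(calls < 0L)
  d <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  if (!has_missing && method == "allele_sharing") {
    d <- as.matrix(stats::dist(calls, method = "manhattan")) /
      (2 * n_sites(gm))
    dimnames(d) <- list(gm$samples, gm$samples)
  } else {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ok <- calls[i, ] >= 0L & calls[j, ] >= 0L
        if (!any(ok))
          stop("samples ", gm$samples[i], " and ", gm$samples[j],
               " share no genotyped sites")
        dij <- if (method == "allele_sharing")
          mean(abs(calls[i, ok] - calls[j, ok])) / 2
        else mean(calls[i, ok] != calls[j, ok])
        d[i, j] <- d[j, i] <- dij
      }
    }
  }
  class(d) <- c("dist_matrix", "matrix", "array")
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via [ape::nj()]). On an additive distance
#' matrix the leaf-to-leaf path lengths of the returned tree reproduce the
#' input exactly. Negative branch lengths are retained (flagged via the
#' `negative_branches` attribute) rather than clamped, preserving that
#' inverse property.
#'
#' @param dm Symmetric distance matrix with zero diagonal (sample ids as
#'   dimnames).
#' @return An [ape::phylo] tree (unrooted for >= 3 leaves).
#' @export
neighbor_joining <- function(dm) {
  dm <- unclass(dm)
  if (!isSymmetric(unname(dm)))
    stop("distance matrix must be symmetric")
  if (any(diag(dm) != 0))
    stop("distance matrix must have a zero diagonal")
  if (nrow(dm) < 3) stop("neighbor joining needs at least 3 samples")
  tree <- ape::nj(stats::as.dist(dm))
  attr(tree, "negative_branches") <- sum(tree$edge.length < 0)
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples sites with replacement, rebuilds the tree per replicate, and
#' reports for each internal edge of the full-data tree the fraction of
#' replicates containing the same bipartition. Supports land in
#' `tree$node.label` (root label left empty).
#'
#' @param gm A `genotype_matrix`.
#' @param reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param method Distance method, see [pairwise_distance()].
#' @param sampler Function drawing a site index vector given the site
#'   count; the default samples with replacement. (Passing
#'   `seq_len` yields identity resamples, for which every support is 1.)
#' @return List with `tree` (the full-data tree, `node.label` = support
#'   fractions) and `support` (numeric vector per internal node, `NA` for
#'   the root).
#' @export
bootstrap_support <- function(gm, reps = 1000, seed = 1,
                              method = "allele_sharing",
                              sampler = function(s) sample.int(s, replace = TRUE)) {
  if (reps < 1) stop("reps must be >= 1")
  tree <- neighbor_joining(pairwise_distance(gm, method = method))
  set.seed(seed)
  boots <- vector("list", reps)
  for (r in seq_len(reps)) {
    idx <- sampler(n_sites(gm))
    calls <- gm$calls[, idx, drop = FALSE]
    boots[[r]] <- neighbor_joining(pairwise_distance_raw(calls, gm$samples,
                                                         method))
  }
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  support <- counts / reps
  support[1L] <- NA # root partition is trivial
  tree$node.label <- ifelse(is.na(support), "",
                            format(round(support, 3), trim = TRUE))
  list(tree = tree, support = support)
}

# distance on a raw call matrix (bootstrap path avoids rebuilding
# genotype_matrix objects, whose site-order validation does not apply to
# resampled columns)
pairwise_distance_raw <- function(calls, samples, method) {
  n <- nrow(calls)
  if (!any(calls < 0L) && method == "allele_sharing") {
    d <- as.matrix(stats::dist(calls, method = "manhattan")) /
      (2 * ncol(calls))
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ok <- calls[i, ] >= 0L & calls[j, ] >= 0L
        d[i, j] <- d[j, i] <- if (method == "allele_sharing")
          mean(abs(calls[i, ok] - calls[j, ok])) / 2
        else mean(calls[i, ok] != calls[j, ok])
      }
    }
  }
  dimnames(d) <- list(samples, samples)
  d
}

#' Write a tree in Newick format (support values as node labels)
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a distance matrix in square PHYLIP format
#' @param dm Symmetric distance matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(dm, path) {
  dm <- unclass(dm)
  n <- nrow(dm)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i)
               paste0(formatC(rownames(dm)[i], width = -10),
                      paste(formatC(dm[i, ], format = "f", digits = 6),
                            collapse = " ")), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write PCA coordinates as TSV
#' @param pca A `genotype_pca` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pca_tsv <- function(pca, path) {
  d <- data.frame(sample = rownames(pca$coords), pca$coords,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
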