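#' Read QTL intervals from a BED-like file
#'
#' @param path BED file: `chrom  start  end  trait` (0-based half-open), an
#'   optional fifth column gives a source id.
#' @return Data frame `trait`, `chrom`, `start`, `end`, `source_id`.
#' @export
read_qtl_bed <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 4) stop("QTL BED needs at least 4 columns")
  out <- data.frame(trait = d[[4]], chrom = d[[1]], start = d[[2]],
                    end = d[[3]],
                    source_id = if (ncol(d) >= 5) d[[5]]
                                else sprintf("qtl%03d", seq_len(nrow(d))),
                    stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) stop("QTL intervals need end > start")
  out
}

#' Keep sweep regions that contain at least one fixation locus
#'
#' @param regions A `sweep_regions` data frame.
#' @param loci A `fixation_loci` data frame.
#' @return The subset of `regions` containing `>= 1` locus.
#' @export
filter_regions_by_fixation <- function(regions, loci) {
  if (!nrow(regions)) return(regions)
  keep <- vapply(seq_len(nrow(regions)), function(k)
    any(loci$chrom == regions$chrom[k] & loci$pos > regions$start[k] &
          loci$pos <= regions$end[k]), logical(1))
  regions[keep, , drop = FALSE]
}

#' Narrow QTL intervals by selective regions
#'
#' For each QTL the retained footprint is the union of its intersections
#' with the supplied regions (typically sweep regions carrying fixation
#' loci); QTLs with an empty footprint are dropped. Totals are computed on
#' interval unions, so overlapping QTLs are not double counted.
#'
#' @param qtls Data frame from [read_qtl_bed()].
#' @param regions Qualifying regions (`chrom`, `start`, `end`; 0-based
#'   half-open), e.g. [filter_regions_by_fixation()] output.
#' @return List with `narrowed` (per retained QTL: trait, chrom, start,
#'   end of each retained piece, source_id) and `summary` (`input_mb`,
#'   `retained_mb`, `n_qtl`, `n_qtl_retained`, `traits_hit`).
#' @export
narrow_qtl <- function(qtls, regions) {
  union_width <- function(d) {
    if (!nrow(d)) return(0)
    tot <- 0
    for (ch in unique(d$chrom)) {
      s <- d[d$chrom == ch, ]
      tot <- tot + sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(s$start + 1L, s$end))))
    }
    tot
  }
  pieces <- list()
  for (k in seq_len(nrow(qtls))) {
    r <- regions[regions$chrom == qtls$chrom[k], , drop = FALSE]
    if (!nrow(r)) next
    qr <- IRanges::IRanges(qtls$start[k] + 1L, qtls$end[k])
    rr <- IRanges::reduce(IRanges::IRanges(r$start + 1L, r$end))
    hit <- IRanges::intersect(qr, rr)
    if (!length(hit)) next
    pieces[[length(pieces) + 1L]] <- data.frame(
      trait = qtls$trait[k], chrom = qtls$chrom[k],
      start = IRanges::start(hit) - 1L, end = IRanges::end(hit),
      source_id = qtls$source_id[k], stringsAsFactors = FALSE)
  }
  narrowed <- if (length(pieces)) do.call(rbind, pieces)
              else data.frame(trait = character(), chrom = character(),
                              start = integer(), end = integer(),
                              source_id = character())
  list(narrowed = narrowed,
       summary = list(
         input_mb = union_width(qtls) / 1e6,
         retained_mb = union_width(narrowed) / 1e6,
         n_qtl = nrow(qtls),
         n_qtl_retained = length(unique(narrowed$source_id)),
         traits_hit = sort(unique(narrowed$trait))))
}

#' Genes overlapping a set of regions
#'
#' Any-overlap rule: a gene qualifies when its span (min to max CDS
#' coordinate) intersects a region.
#'
#' @param gene_models A `gene_models` data frame.
#' @param regions Regions (`chrom`, `start`, `end`, 0-based half-open).
#' @return Character vector of gene ids.
#' @export
genes_in_regions <- function(gene_models, regions) {
  span <- do.call(rbind, lapply(split(gene_models, gene_models$gene_id),
                                function(g) data.frame(
                                  gene_id = g$gene_id[1L],
                                  chrom = g$chrom[1L],
                                  start = min(g$start), end = max(g$end))))
  hit <- vapply(seq_len(nrow(span)), function(k)
    any(regions$chrom == span$chrom[k] & regions$start < span$end[k] &
          regions$end > span$start[k] - 1L), logical(1))
  sort(span$gene_id[hit])
}

#' Fisher's exact (hypergeometric) gene-category enrichment
#'
#' One-sided over-representation test per category with
#' Benjamini-Hochberg q-values across all tested categories.
#'
#' @param selected_genes Character vector, a subset of `background_genes`.
#' @param background_genes Character vector: the gene universe (must be an
#'   explicit input; enrichment is only meaningful relative to a stated
#'   background).
#' @param categories Data frame `gene`, `category` (a gene may appear in
#'   several categories). Categories with no background gene are skipped.
#' @return Data frame per category: `category`, `k` (selected in category),
#'   `K` (selected total), `m` (background in category), `M` (background
#'   total), `odds_ratio`, `p_fisher`, `q_bh`.
#' @export
fisher_enrichment <- function(selected_genes, background_genes, categories) {
  selected_genes <- unique(selected_genes)
  background_genes <- unique(background_genes)
  extra <- setdiff(selected_genes, background_genes)
  if (length(extra))
    stop("selected genes missing from background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  categories <- categories[categories$gene %in% background_genes, ,
                           drop = FALSE]
  cats <- sort(unique(categories$category))
  bigM <- length(background_genes)
  bigK <- length(selected_genes)
  rows <- lapply(cats, function(cat) {
    genes_cat <- unique(categories$gene[categories$category == cat])
    m <- length(genes_cat)
    k <- length(intersect(selected_genes, genes_cat))
    p <- stats::phyper(k - 1, m, bigM - m, bigK, lower.tail = FALSE)
    a <- k; b <- bigK - k; cc <- m - k; dd <- bigM - bigK - (m - k)
    or <- (a * dd) / (b * cc)
    data.frame(category = cat, k = k, K = bigK, m = m, M = bigM,
               odds_ratio = or, p_fisher = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_bh <- bh_fdr(out$p_fisher)
  out
}

#' Permutation test for gene-category enrichment
#'
#' Draws random gene sets of the observed size from the background and
#' reports, per category, the add-one empirical probability of seeing at
#' least the observed category count:
#' `(1 + #{k* >= k_obs}) / (reps + 1)`.
#'
#' @inheritParams fisher_enrichment
#' @param reps Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return Data frame `category`, `k`, `p_perm`.
#' @export
permutation_enrichment <- function(selected_genes, background_genes,
                                   categories, reps = 1000, seed = 1) {
  if (reps < 100) stop("need at least 100 permutations")
  selected_genes <- unique(selected_genes)
  background_genes <- unique(background_genes)
  categories <- categories[categories$gene %in% background_genes, ,
                           drop = FALSE]
  cats <- sort(unique(categories$category))
  member <- vapply(cats, function(cat)
    background_genes %in% categories$gene[categories$category == cat],
    logical(length(background_genes)))
  k_obs <- colSums(member[background_genes %in% selected_genes, ,
                          drop = FALSE])
  set.seed(seed)
  n_sel <- length(selected_genes)
  exceed <- integer(length(cats))
  for (r in seq_len(reps)) {
    idx <- sample.int(length(background_genes), n_sel)
    k_star <- colSums(member[idx, , drop = FALSE])
    exceed <- exceed + (k_star >= k_obs)
  }
  data.frame(category = cats, k = as.integer(k_obs),
             p_perm = (1 + exceed) / (reps + 1), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p Numeric vector of P values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Read a gene-to-category TSV (columns `gene`, `category`)
#' @param path Input path.
#' @return Data frame `gene`, `category`.
#' @export
read_gene_categories <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("gene", "category") %in% names(d)))
    stop("gene-category table needs columns 'gene' and 'category'")
  d
}
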