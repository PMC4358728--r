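#' Detect nucleotide-fixation loci
#'
#' A fixation locus is a SNV with a single (unique) genotype across every
#' sample of the focal group while the comparison group shows at least two
#' distinct genotypes. Detection runs on a consensus matrix without missing
#' calls — produce one with [assign_ml_genotypes()] first. A uniform
#' heterozygous focal group satisfies the definition but is biologically
#' implausible and is flagged.
#'
#' @param gm A `genotype_matrix` with no missing calls among the two groups.
#' @param manifest A `population_manifest`.
#' @param focal_group Group required to be uniform (e.g. `"cultivated"`).
#' @param other_group Group required to be polymorphic (e.g. `"wild"`).
#' @param regions Optional `sweep_regions` data frame; loci are annotated
#'   with membership (`in_sweep`, `region_id`).
#' @return Data frame of class `fixation_loci`: `chrom`, `pos`, `ref`,
#'   `alt`, `fixed_population`, `fixed_genotype`, `other_population`,
#'   `implausible_het`, `wild_alt_freq` (`NA` without wild samples),
#'   `in_sweep`, `region_id`, `effect` (initially `"unclassified"`),
#'   `site_index` (column in `gm`).
#' @export
detect_fixations <- function(gm, manifest, focal_group = "cultivated",
                             other_group = "wild", regions = NULL) {
  focal <- subset_population(gm, manifest, focal_group)
  other <- subset_population(gm, manifest, other_group)
  if (any(focal$calls < 0L) || any(other$calls < 0L))
    stop("missing calls present; run assign_ml_genotypes() to obtain a ",
         "consensus matrix first")
  f_first <- focal$calls[rep(1L, n_samples(focal)), , drop = FALSE]
  uniform_focal <- colSums(focal$calls != f_first) == 0L
  o_first <- other$calls[rep(1L, n_samples(other)), , drop = FALSE]
  poly_other <- colSums(other$calls != o_first) > 0L
  hit <- which(uniform_focal & poly_other)
  fixed_gt <- focal$calls[1L, hit]
  wild_freq <- rep(NA_real_, length(hit))
  if ("wild" %in% manifest$label) {
    wild <- subset_population(gm, manifest, "wild")
    ac <- allele_count_table(wild)
    wild_freq <- ifelse(ac$n_alleles[hit] > 0,
                        ac$alt_count[hit] / ac$n_alleles[hit], NA_real_)
  }
  loci <- data.frame(
    chrom = gm$sites$chrom[hit],
    pos = gm$sites$pos[hit],
    ref = gm$sites$ref[hit],
    alt = gm$sites$alt[hit],
    fixed_population = rep(focal_group, length(hit)),
    fixed_genotype = as.integer(fixed_gt),
    other_population = rep(other_group, length(hit)),
    implausible_het = fixed_gt == 1L,
    wild_alt_freq = wild_freq,
    in_sweep = rep(FALSE, length(hit)),
    region_id = rep(NA_character_, length(hit)),
    effect = rep("unclassified", length(hit)),
    site_index = hit,
    stringsAsFactors = FALSE
  )
  if (!is.null(regions) && nrow(regions) && nrow(loci))
    loci <- annotate_regions(loci, regions)
  class(loci) <- c("fixation_loci", "data.frame")
  loci
}

# Mark loci lying inside any region; region ids are chrom:start-end.
annotate_regions <- function(loci, regions) {
  rid <- sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  for (k in seq_len(nrow(regions))) {
    inside <- loci$chrom == regions$chrom[k] &
      loci$pos > regions$start[k] & loci$pos <= regions$end[k]
    loci$in_sweep[inside] <- TRUE
    loci$region_id[inside] <- rid[k]
  }
  loci
}

#' Fixation density per window, genome-wide versus inside sweeps
#'
#' Counts fixation loci in (typically tiling, step = window) windows and
#' stratifies windows by overlap with sweep regions. The summary contrasts
#' mean per-window counts inside regions against the genome-wide mean.
#'
#' @param loci A `fixation_loci` data frame.
#' @param regions A `sweep_regions` data frame (may be empty).
#' @param windows Window data frame (0-based half-open).
#' @return List with `table` (windows plus `n_fixations`, `in_region`) and
#'   `summary` (mean densities and their ratio).
#' @export
fixation_density <- function(loci, regions, windows) {
  tab <- windows
  tab$n_fixations <- 0L
  if (nrow(loci)) {
    for (k in seq_len(nrow(windows))) {
      tab$n_fixations[k] <- sum(loci$chrom == windows$chrom[k] &
                                  loci$pos > windows$start[k] &
                                  loci$pos <= windows$end[k])
    }
  }
  tab$in_region <- FALSE
  if (!is.null(regions) && nrow(regions)) {
    for (k in seq_len(nrow(regions))) {
      tab$in_region <- tab$in_region |
        (tab$chrom == regions$chrom[k] & tab$start < regions$end[k] &
           tab$end > regions$start[k])
    }
  }
  mean_in <- if (any(tab$in_region)) mean(tab$n_fixations[tab$in_region])
             else NA_real_
  mean_genome <- mean(tab$n_fixations)
  list(table = tab,
       summary = list(mean_in_region = mean_in,
                      mean_genome = mean_genome,
                      ratio = if (is.na(mean_in) || mean_genome == 0)
                        NA_real_ else mean_in / mean_genome))
}

#' Wild-population frequency spectrum of cultivar-fixed loci
#'
#' The spectrum of wild alternate-allele counts at loci fixed in cultivars
#' reflects the standing frequency of those alleles before domestication.
#'
#' @param gm Full `genotype_matrix` (all populations).
#' @param manifest A `population_manifest`.
#' @param loci `fixation_loci` fixed in the cultivated group (must carry
#'   `site_index`).
#' @return As [sfs()] on the wild sub-matrix at those sites, with attribute
#'   `n_skipped` for loci that could not be placed.
#' @export
wild_frequency_of_fixed <- function(gm, manifest, loci) {
  wild <- subset_population(gm, manifest, "wild")
  idx <- loci$site_index
  ok <- !is.na(idx) & idx >= 1L & idx <= n_sites(wild)
  spec <- sfs(wild, site_subset = idx[ok])
  attr(spec, "n_skipped") <- sum(!ok)
  spec
}

#' Read gene models (CDS) from a GFF3 file
#'
#' Imports CDS features with `rtracklayer` and organizes them per
#' transcript. When a gene has several transcripts the longest-CDS
#' transcript represents the gene (per-transcript mode: keep all).
#'
#' @param path GFF3 file.
#' @param longest_per_gene Keep only the longest-CDS transcript of each
#'   gene.
#' @return Data frame of class `gene_models` with columns `gene_id`,
#'   `transcript_id`, `chrom`, `strand`, `start`, `end` (1-based
#'   inclusive), `phase`.
#' @export
read_gene_models <- function(path, longest_per_gene = TRUE) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  if (!length(cds)) stop("no CDS features in ", path)
  parent <- vapply(cds$Parent, function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))
  tab <- data.frame(
    transcript_id = parent,
    chrom = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(GenomicRanges::strand(cds)),
    start = GenomicRanges::start(cds),
    end = GenomicRanges::end(cds),
    phase = as.integer(cds$phase),
    stringsAsFactors = FALSE
  )
  mrna <- gr[gr$type %in% c("mRNA", "transcript")]
  gene_of <- stats::setNames(
    vapply(mrna$Parent, function(p)
      if (length(p)) p[[1L]] else NA_character_, character(1)),
    mrna$ID)
  tab$gene_id <- gene_of[tab$transcript_id]
  tab$gene_id[is.na(tab$gene_id)] <- tab$transcript_id[is.na(tab$gene_id)]
  if (longest_per_gene) {
    len <- tapply(tab$end - tab$start + 1L, tab$transcript_id, sum)
    tx_gene <- tapply(tab$gene_id, tab$transcript_id, `[`, 1L)
    best <- tapply(names(len), tx_gene[names(len)], function(txs)
      txs[which.max(len[txs])])
    tab <- tab[tab$transcript_id %in% unlist(best), ]
  }
  tab <- tab[order(tab$chrom, tab$start), ]
  rownames(tab) <- NULL
  class(tab) <- c("gene_models", "data.frame")
  tab
}

#' Classify the coding effect of one substitution
#'
#' Locates the site in the (spliced, phase-adjusted) CDS of overlapping
#' gene models, assembles the codon containing it — reverse-complementing
#' on the minus strand and joining adjacent CDS segments across splice
#' junctions — and translates reference and alternate codons with the
#' standard nuclear code.
#'
#' @param chrom,pos,ref,alt The substitution (1-based position, single
#'   nucleotides).
#' @param gene_models A `gene_models` data frame.
#' @param genome A `DNAStringSet` (names = chromosomes), e.g. from
#'   [Biostrings::readDNAStringSet()].
#' @return List with `effect` (`"noncoding"`, `"synonymous"`,
#'   `"nonsynonymous"` or `"unclassified"`), `gene_id`, `transcript_id`,
#'   `codon_ref`, `codon_alt`, `aa_ref`, `aa_alt`.
#' @export
classify_coding_effect <- function(chrom, pos, ref, alt, gene_models,
                                   genome) {
  hit <- gene_models$chrom == chrom & gene_models$start <= pos &
    gene_models$end >= pos
  if (!any(hit))
    return(list(effect = "noncoding", gene_id = NA_character_,
                transcript_id = NA_character_, codon_ref = NA, codon_alt = NA,
                aa_ref = NA, aa_alt = NA))
  tx <- gene_models$transcript_id[hit][1L]
  seg <- gene_models[gene_models$transcript_id == tx, , drop = FALSE]
  minus <- seg$strand[1L] == "-"
  seg <- seg[order(seg$start, decreasing = minus), , drop = FALSE]
  chrseq <- genome[[chrom]]
  pieces <- lapply(seq_len(nrow(seg)), function(k) {
    s <- Biostrings::subseq(chrseq, seg$start[k], seg$end[k])
    if (minus) Biostrings::reverseComplement(s) else s
  })
  cds <- do.call(Biostrings::xscat, pieces)
  offset <- seg$phase[1L]
  if (is.na(offset)) offset <- 0L
  usable_len <- length(cds) - offset
  if (usable_len %% 3L != 0L) {
    warning("CDS length of ", tx, " not a multiple of 3; effect unclassified")
    return(list(effect = "unclassified", gene_id = seg$gene_id[1L],
                transcript_id = tx, codon_ref = NA, codon_alt = NA,
                aa_ref = NA, aa_alt = NA))
  }
  # position of the site within the spliced CDS (1-based)
  seg_k <- which(seg$start <= pos & seg$end >= pos)[1L]
  prior <- if (seg_k > 1L) sum(seg$end[1:(seg_k - 1L)] -
                                 seg$start[1:(seg_k - 1L)] + 1L) else 0L
  within <- if (minus) seg$end[seg_k] - pos + 1L else pos - seg$start[seg_k] + 1L
  cds_pos <- prior + within
  cds_pos0 <- cds_pos - offset
  if (cds_pos0 < 1L)
    return(list(effect = "unclassified", gene_id = seg$gene_id[1L],
                transcript_id = tx, codon_ref = NA, codon_alt = NA,
                aa_ref = NA, aa_alt = NA))
  codon_idx <- (cds_pos0 - 1L) %/% 3L
  codon_start <- offset + codon_idx * 3L + 1L
  codon_ref <- as.character(Biostrings::subseq(cds, codon_start,
                                               codon_start + 2L))
  pos_in_codon <- cds_pos - codon_start + 1L
  ref_tx <- if (minus) complement_base(ref) else ref
  alt_tx <- if (minus) complement_base(alt) else alt
  if (substr(codon_ref, pos_in_codon, pos_in_codon) != ref_tx)
    warning("reference allele at ", chrom, ":", pos,
            " does not match the genome sequence")
  codon_alt <- codon_ref
  substr(codon_alt, pos_in_codon, pos_in_codon) <- alt_tx
  aa_ref <- Biostrings::GENETIC_CODE[[codon_ref]]
  aa_alt <- Biostrings::GENETIC_CODE[[codon_alt]]
  effect <- if (identical(aa_ref, aa_alt)) "synonymous" else "nonsynonymous"
  list(effect = effect, gene_id = seg$gene_id[1L], transcript_id = tx,
       codon_ref = codon_ref, codon_alt = codon_alt, aa_ref = aa_ref,
       aa_alt = aa_alt)
}

complement_base <- function(x) {
  c(A = "T", C = "G", G = "C", T = "A")[[x]]
}

#' Classify coding effects for a table of fixation loci
#'
#' @param loci A `fixation_loci` data frame.
#' @param gene_models A `gene_models` data frame.
#' @param genome A `DNAStringSet`.
#' @return `loci` with `effect` and `gene_id` columns filled in.
#' @export
classify_effects <- function(loci, gene_models, genome) {
  if (!nrow(loci)) {
    loci$gene_id <- character(0)
    return(loci)
  }
  res <- lapply(seq_len(nrow(loci)), function(k)
    classify_coding_effect(loci$chrom[k], loci$pos[k], loci$ref[k],
                           loci$alt[k], gene_models, genome))
  loci$effect <- vapply(res, `[[`, character(1), "effect")
  loci$gene_id <- vapply(res, function(r)
    if (is.na(r$gene_id)) NA_character_ else r$gene_id, character(1))
  loci
}

#' Write fixation loci as TSV
#' @param loci A `fixation_loci` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixations_tsv <- function(loci, path) {
  utils::write.table(as.data.frame(loci), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
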