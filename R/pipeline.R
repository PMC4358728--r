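#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis: either a simulation
#' request (`sim`) or paths to real inputs, the window geometry, the scan
#' thresholds, estimator flags and seeds.
#'
#' @param sim A `sim_config`, or `NULL` when `input` paths are given.
#' @param input `NULL`, or a named list of paths: `vcf`, `manifest`, and
#'   optionally `gff3`, `fasta`, `qtl`, `categories`, `chrom_lengths`
#'   (named numeric vector; required for real inputs, derived from the
#'   config for simulations).
#' @param window,step Sliding-window geometry in bp (defaults 20 kb / 2 kb).
#' @param alpha Per-statistic level of the domestication scan (default
#'   0.05).
#' @param alpha_improvement Bonferroni-corrected PBS threshold (default
#'   0.001).
#' @param exclude Sample ids dropped before the scans.
#' @param fst_estimator `"hudson"` or `"wc"`.
#' @param use_ml_consensus Re-derive consensus genotypes from likelihoods
#'   before fixation calling (when likelihoods are available).
#' @param bootstrap_reps Bootstrap replicates for the NJ tree.
#' @param rarefaction_reps Replicates per rarefaction point.
#' @param out_dir Output directory.
#' @param seed Master seed for every downstream stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), input = NULL,
                            window = 20000, step = 2000, alpha = 0.05,
                            alpha_improvement = 0.001,
                            exclude = character(),
                            fst_estimator = "hudson",
                            use_ml_consensus = FALSE,
                            bootstrap_reps = 100, rarefaction_reps = 20,
                            out_dir = tempfile("divsweep_run"), seed = 1) {
  cfg <- list(sim = sim, input = input, window = window, step = step,
              alpha = alpha, alpha_improvement = alpha_improvement,
              exclude = exclude, fst_estimator = fst_estimator,
              use_ml_consensus = use_ml_consensus,
              bootstrap_reps = bootstrap_reps,
              rarefaction_reps = rarefaction_reps,
              out_dir = out_dir, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every invariant and returns the full list of problems rather than
#' failing at the first one; an empty character vector means the
#' configuration is valid.
#'
#' @param cfg A `pipeline_config`.
#' @return Character vector of error messages (length 0 when valid).
#' @export
validate_config <- function(cfg) {
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(cfg$window >= cfg$step, "window must be >= step")
  chk(cfg$step > 0, "step must be > 0")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must lie in (0, 1)")
  chk(cfg$alpha_improvement > 0 && cfg$alpha_improvement < 1,
      "alpha_improvement must lie in (0, 1)")
  chk(cfg$fst_estimator %in% c("hudson", "wc"),
      "fst_estimator must be 'hudson' or 'wc'")
  chk(cfg$bootstrap_reps >= 1, "bootstrap_reps must be >= 1")
  chk(is.null(cfg$sim) || inherits(cfg$sim, "sim_config"),
      "sim must be NULL or a sim_config")
  chk(!is.null(cfg$sim) || !is.null(cfg$input),
      "either a simulation config or input paths are required")
  if (!is.null(cfg$input)) {
    chk(all(c("vcf", "manifest") %in% names(cfg$input)),
        "input needs at least 'vcf' and 'manifest' paths")
    chk(!is.null(cfg$input$chrom_lengths),
        "input needs 'chrom_lengths' (named vector)")
  }
  if (!is.null(cfg$sim)) {
    ok <- tryCatch({ validate_sim_config(cfg$sim); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) errs <- c(errs, paste0("sim: ", ok))
  }
  errs
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate or load inputs; (2) windowed diversity per
#' population and the diversity-reduction summary; (3) domestication and
#' improvement sweep scans, merged into regions; (4) consensus genotypes
#' and nucleotide-fixation loci for both transitions, coding-effect
#' classification and fixation density; (5) rarefaction curves and the
#' wild-frequency spectrum of cultivar-fixed loci; (6) PCA, distance
#' matrix, NJ tree with bootstrap supports; (7) QTL narrowing and
#' gene-category enrichment (when annotation inputs exist). All tables are
#' written under `cfg$out_dir`; re-running with an identical configuration
#' reproduces identical files.
#'
#' @param cfg A `pipeline_config`.
#' @return A `run_report` list: per-stage record counts, parameters,
#'   warnings and the diversity-reduction summary. Serialized as
#'   `report.json` in the output directory.
#' @export
run_pipeline <- function(cfg) {
  errs <- validate_config(cfg)
  if (length(errs))
    stop("invalid configuration:\n", paste("-", errs, collapse = "\n"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = cfg[c("window", "step", "alpha",
                                    "alpha_improvement", "fst_estimator",
                                    "seed")],
                 warnings = character())
  warn <- function(msg) {
    report$warnings <<- c(report$warnings, msg)
    message("[divsweep] ", msg)
  }

  # ---- stage 1: data -------------------------------------------------
  if (!is.null(cfg$sim)) {
    sim <- simulate_populations(cfg$sim)
    fix_dir <- file.path(cfg$out_dir, "inputs")
    paths <- write_fixtures(sim, fix_dir)
    gm <- sim$genotypes
    gl <- sim$likelihoods
    manifest <- sim$manifest
    truth <- sim$truth
    chrom_lengths <- stats::setNames(
      rep(cfg$sim$chrom_length, cfg$sim$n_chrom), sim_chrom_names(cfg$sim))
    gene_models <- read_gene_models(paths[["gff3"]])
    genome <- Biostrings::readDNAStringSet(paths[["fasta"]])
    names(genome) <- sub(" .*", "", names(genome))
    qtls <- read_qtl_bed(paths[["qtl"]])
    cats <- read_gene_categories(paths[["categories"]])
  } else {
    inp <- cfg$input
    vr <- read_vcf(inp$vcf)
    gm <- vr$genotypes
    gl <- vr$likelihoods
    manifest <- read_manifest(inp$manifest)
    truth <- NULL
    chrom_lengths <- inp$chrom_lengths
    gene_models <- if (!is.null(inp$gff3)) read_gene_models(inp$gff3)
    genome <- if (!is.null(inp$fasta)) {
      g <- Biostrings::readDNAStringSet(inp$fasta)
      names(g) <- sub(" .*", "", names(g))
      g
    }
    qtls <- if (!is.null(inp$qtl)) read_qtl_bed(inp$qtl)
    cats <- if (!is.null(inp$categories)) read_gene_categories(inp$categories)
  }
  validate_manifest(gm, manifest)
  report$n_samples <- n_samples(gm)
  report$n_sites <- n_sites(gm)

  # ---- stage 2: diversity -------------------------------------------
  windows <- sliding_windows(chrom_lengths, cfg$window, cfg$step)
  genome_len <- sum(chrom_lengths)
  groups <- c("wild", "landrace", "elite", "cultivated")
  have <- vapply(groups, function(g)
    length(intersect(population_samples(manifest, g), gm$samples)) > 0,
    logical(1))
  pi_by_group <- rep(NA_real_, length(groups))
  names(pi_by_group) <- groups
  for (g in groups[have]) {
    sub <- subset_population(gm, manifest, g)
    pi_by_group[g] <- genome_theta_pi(sub, genome_len)
    wd <- window_diversity(sub, windows)
    utils::write.table(wd, file.path(cfg$out_dir,
                                     sprintf("diversity_%s.tsv", g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report$theta_pi <- as.list(pi_by_group)
  if (all(have)) {
    report$diversity_reduction <- diversity_reduction_summary(
      pi_by_group["wild"], pi_by_group["landrace"], pi_by_group["elite"],
      pi_by_group["cultivated"])
  }

  # ---- stage 3: sweep scans -----------------------------------------
  dom <- domestication_scan(gm, manifest, windows, alpha = cfg$alpha,
                            exclude = cfg$exclude)
  write_scan_tsv(dom, file.path(cfg$out_dir, "scan_domestication.tsv"))
  dom_regions <- merge_windows(dom)
  write_regions_bed(dom_regions,
                    file.path(cfg$out_dir, "regions_domestication.bed"))
  report$domestication <- list(windows_tested = sum(!is.na(dom$p_ratio)),
                               windows_selected = sum(dom$selected),
                               n_regions = nrow(dom_regions),
                               total_mb = attr(dom_regions, "total_mb"))
  imp_regions <- NULL
  if (have["landrace"] && have["elite"]) {
    imp <- improvement_scan(gm, manifest, windows,
                            alpha_corrected = cfg$alpha_improvement,
                            exclude = cfg$exclude,
                            estimator = cfg$fst_estimator)
    write_scan_tsv(imp, file.path(cfg$out_dir, "scan_improvement.tsv"))
    imp_regions <- merge_windows(imp)
    write_regions_bed(imp_regions,
                      file.path(cfg$out_dir, "regions_improvement.bed"))
    report$improvement <- list(windows_tested = attr(imp, "n_tested"),
                               windows_selected = sum(imp$selected),
                               n_regions = nrow(imp_regions),
                               total_mb = attr(imp_regions, "total_mb"))
  } else {
    warn("improvement scan skipped: landrace or elite population empty")
  }

  # ---- stage 4: fixation --------------------------------------------
  consensus <- gm
  if (cfg$use_ml_consensus && !is.null(gl)) {
    consensus <- assign_ml_genotypes(gl)
    report$ml_consensus <- list(n_ties = attr(consensus, "n_ties"),
                                n_flagged = attr(consensus, "n_flagged"))
  }
  ok_fix <- !any(consensus$calls < 0L)
  fix_dom <- NULL
  if (ok_fix) {
    fix_dom <- detect_fixations(consensus, manifest, "cultivated", "wild",
                                regions = dom_regions)
    if (!is.null(gene_models) && !is.null(genome))
      fix_dom <- classify_effects(fix_dom, gene_models, genome)
    write_fixations_tsv(fix_dom,
                        file.path(cfg$out_dir, "fixations_cultivated.tsv"))
    dens_windows <- sliding_windows(chrom_lengths, cfg$window, cfg$window)
    dens <- fixation_density(fix_dom, dom_regions, dens_windows)
    utils::write.table(dens$table,
                       file.path(cfg$out_dir, "fixation_density.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$fixation <- list(
      n_loci_cultivated = nrow(fix_dom),
      n_in_sweep = sum(fix_dom$in_sweep),
      n_nonsynonymous = sum(fix_dom$effect == "nonsynonymous"),
      n_synonymous = sum(fix_dom$effect == "synonymous"),
      density_ratio = dens$summary$ratio)
    if (!is.null(imp_regions) && have["landrace"] && have["elite"]) {
      fix_imp <- detect_fixations(consensus, manifest, "elite", "landrace",
                                  regions = imp_regions)
      write_fixations_tsv(fix_imp,
                          file.path(cfg$out_dir, "fixations_elite.tsv"))
      report$fixation$n_loci_elite <- nrow(fix_imp)
    }
    spec <- wild_frequency_of_fixed(gm, manifest, fix_dom)
    utils::write.table(spec, file.path(cfg$out_dir, "sfs_fixed_wild.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    warn("fixation calling skipped: consensus matrix has missing calls")
  }

  # ---- stage 5: rarefaction -----------------------------------------
  for (g in groups[have & groups %in% c("wild", "cultivated")]) {
    n_g <- length(intersect(population_samples(manifest, g), gm$samples))
    ks <- unique(pmin(n_g, c(1, 2, 3, 5, 8, 12, 18, 25, n_g)))
    curve <- snv_accumulation(gm, manifest, g, ks,
                              reps = cfg$rarefaction_reps,
                              seed = cfg$seed + 17L)
    utils::write.table(curve,
                       file.path(cfg$out_dir,
                                 sprintf("rarefaction_%s.tsv", g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # ---- stage 6: structure -------------------------------------------
  pca <- pca_genotypes(gm, n_components = 10)
  write_pca_tsv(pca, file.path(cfg$out_dir, "pca.tsv"))
  dm <- pairwise_distance(gm)
  write_phylip_dist(dm, file.path(cfg$out_dir, "distances.phylip"))
  bs <- bootstrap_support(gm, reps = cfg$bootstrap_reps,
                          seed = cfg$seed + 23L)
  write_newick(bs$tree, file.path(cfg$out_dir, "nj_tree.nwk"))
  report$structure <- list(
    pc1_var = unname(pca$explained_variance[1]),
    n_boot = cfg$bootstrap_reps,
    min_support = suppressWarnings(min(bs$support, na.rm = TRUE)))

  # ---- stage 7: QTL and enrichment ----------------------------------
  if (!is.null(qtls) && !is.null(gene_models) && ok_fix &&
      !is.null(fix_dom)) {
    qualifying <- filter_regions_by_fixation(dom_regions, fix_dom)
    nq <- narrow_qtl(qtls, qualifying)
    utils::write.table(nq$narrowed,
                       file.path(cfg$out_dir, "qtl_narrowed.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$qtl <- nq$summary
    if (!is.null(cats)) {
      background <- sort(unique(gene_models$gene_id))
      selected <- genes_in_regions(gene_models, qualifying)
      if (length(selected)) {
        enr <- fisher_enrichment(selected, background, cats)
        perm <- permutation_enrichment(selected, background, cats,
                                       reps = 1000, seed = cfg$seed + 31L)
        enr$p_perm <- perm$p_perm[match(enr$category, perm$category)]
        utils::write.table(enr, file.path(cfg$out_dir, "enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        report$enrichment <- list(n_categories = nrow(enr),
                                  n_significant = sum(enr$q_bh < 0.05))
      } else warn("enrichment skipped: no genes overlap qualifying regions")
    }
  }

  if (!is.null(truth)) {
    report$truth <- list(n_swept_regions = nrow(truth$swept_regions),
                         n_fixed_loci = nrow(truth$fixed_loci))
  }
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report),
                       file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  report
}
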