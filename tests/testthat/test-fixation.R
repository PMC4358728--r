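test_that("fixation definition: uniform focal, polymorphic comparison", {
  # site 1: focal all hom-alt, other mixed -> fixation
  # site 2: focal mixed -> no fixation
  # site 3: both groups uniform (different codes) -> not polymorphic -> no
  calls <- rbind(c(2L, 0L, 0L),
                 c(2L, 1L, 0L),
                 c(0L, 0L, 1L),
                 c(2L, 0L, 1L))
  gm <- make_gm(calls)
  man <- population_manifest(gm$samples,
                             c("landrace", "elite", "wild", "wild"))
  loci <- detect_fixations(gm, man, "cultivated", "wild")
  expect_equal(loci$pos, gm$sites$pos[1])
  expect_equal(loci$fixed_genotype, 2L)
  expect_equal(loci$wild_alt_freq, 0.5)
  # uniform heterozygous focal group is reported but flagged
  calls2 <- rbind(c(1L), c(1L), c(0L), c(2L))
  gm2 <- make_gm(calls2)
  loci2 <- detect_fixations(gm2, man, "cultivated", "wild")
  expect_true(loci2$implausible_het)
})

test_that("missing calls are rejected with a pointer to ML assignment", {
  gm <- make_gm(rbind(c(-1L), c(0L), c(1L), c(2L)))
  man <- population_manifest(gm$samples,
                             c("landrace", "elite", "wild", "wild"))
  expect_error(detect_fixations(gm, man, "cultivated", "wild"),
               "assign_ml_genotypes")
})

test_that("detected loci equal the brute-force per-site definition", {
  set.seed(23)
  gm <- random_gm(n = 12, s = 50, seed = 23)
  man <- make_manifest(gm, 5, 4)
  for (groups in list(c("cultivated", "wild"), c("wild", "cultivated"),
                      c("elite", "landrace"))) {
    loci <- detect_fixations(gm, man, groups[1], groups[2])
    f_ids <- population_samples(man, groups[1])
    o_ids <- population_samples(man, groups[2])
    fc <- gm$calls[gm$samples %in% f_ids, , drop = FALSE]
    oc <- gm$calls[gm$samples %in% o_ids, , drop = FALSE]
    expected <- integer(0)
    for (j in seq_len(n_sites(gm))) {
      if (length(unique(fc[, j])) == 1L && length(unique(oc[, j])) >= 2L)
        expected <- c(expected, j)
    }
    expect_equal(loci$site_index, expected)
  }
})

test_that("fixed-in-focal and fixed-in-other partition sites consistently", {
  set.seed(29)
  gm <- random_gm(n = 10, s = 80, seed = 29)
  man <- make_manifest(gm, 5, 3)
  a <- detect_fixations(gm, man, "cultivated", "wild")$site_index
  b <- detect_fixations(gm, man, "wild", "cultivated")$site_index
  # a site fixed for one focal choice cannot be fixed for the other unless
  # both groups are uniform, which "polymorphic other" excludes
  expect_length(intersect(a, b), 0)
})

test_that("generator-injected fixations are recovered and density concentrates in sweeps", {
  sw <- data.frame(chrom = "chr1",
                   start = c(100000, 250000, 400000),
                   end = c(140000, 290000, 440000),
                   transition = c("domestication", "domestication",
                                  "improvement"))
  sim <- simulate_populations(test_sim_config(chrom_length = 6e5,
                                              sweep_specs = sw, seed = 13))
  gm <- sim$genotypes
  man <- sim$manifest
  truth <- sim$truth$fixed_loci
  regions <- data.frame(chrom = sw$chrom, start = sw$start, end = sw$end)

  loci_c <- detect_fixations(gm, man, "cultivated", "wild",
                             regions = regions)
  loci_e <- detect_fixations(gm, man, "elite", "landrace")
  dom_truth <- truth[truth$fixed_population == "cultivated", ]
  imp_truth <- truth[truth$fixed_population == "elite", ]
  expect_true(all(dom_truth$pos %in% loci_c$pos))
  expect_true(all(imp_truth$pos %in% loci_e$pos))
  # truth focal loci are annotated as in-sweep
  expect_true(all(loci_c$in_sweep[loci_c$pos %in% dom_truth$pos]))

  windows <- sliding_windows(c(chr1 = 6e5), window = 20000, step = 20000)
  dens <- fixation_density(loci_c, regions, windows)
  expect_equal(sum(dens$table$n_fixations), nrow(loci_c))
  expect_gt(dens$summary$mean_in_region, dens$summary$mean_genome)
  # empty locus table gives all-zero densities
  dens0 <- fixation_density(loci_c[0, ], regions, windows)
  expect_true(all(dens0$table$n_fixations == 0))
})

test_that("wild-frequency spectrum of cultivar-fixed loci is conserved", {
  calls <- rbind(c(2L, 2L), c(2L, 2L), # cultivated fixed alt at both sites
                 c(1L, 0L), c(2L, 1L), c(0L, 0L)) # wild polymorphic
  gm <- make_gm(calls)
  man <- population_manifest(gm$samples,
                             c("landrace", "elite", rep("wild", 3)))
  loci <- detect_fixations(gm, man, "cultivated", "wild")
  spec <- wild_frequency_of_fixed(gm, man, loci)
  expect_equal(sum(spec$n_sites), nrow(loci))
  # wild alt counts are 3/6 and 1/6
  expect_equal(spec$n_sites[spec$count == 3], 1)
  expect_equal(spec$n_sites[spec$count == 1], 1)
})

test_that("coding effects follow the standard code on both strands", {
  # plus-strand gene: CDS 101..130, codon GGA at 101-103
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    paste(rep("T", 100), collapse = ""),
    "GGAGGGAAACCCTTTGGGAAACCCTTTAAA",
    paste(rep("T", 70), collapse = ""))))
  models <- data.frame(gene_id = "g1", transcript_id = "g1.t1",
                       chrom = "chr1", strand = "+", start = 101L,
                       end = 130L, phase = 0L)
  # GGA -> GGG : Gly -> Gly, synonymous (third codon position)
  syn <- classify_coding_effect("chr1", 103, "A", "G", models, genome)
  expect_equal(syn$effect, "synonymous")
  expect_equal(syn$aa_ref, "G")
  # GGA -> GAA : Gly -> Glu, nonsynonymous (second position)
  nonsyn <- classify_coding_effect("chr1", 102, "G", "A", models, genome)
  expect_equal(nonsyn$effect, "nonsynonymous")
  expect_equal(nonsyn$aa_alt, "E")
  # outside every CDS
  expect_equal(classify_coding_effect("chr1", 50, "T", "A", models,
                                      genome)$effect, "noncoding")

  # minus-strand fixture, hand-translated: genome 201..209 = "TTCCATGGC";
  # transcript = revcomp = GCCATGGAA -> Ala Met Glu.
  genome2 <- Biostrings::DNAStringSet(c(chr1 = paste0(
    paste(rep("A", 200), collapse = ""), "TTCCATGGC",
    paste(rep("A", 91), collapse = ""))))
  models2 <- data.frame(gene_id = "g2", transcript_id = "g2.t1",
                        chrom = "chr1", strand = "-", start = 201L,
                        end = 209L, phase = 0L)
  # genome T->C at 206 complements to A->G at base 1 of codon 2:
  # ATG -> GTG, Met -> Val (hand translation)
  eff <- classify_coding_effect("chr1", 206, "T", "C", models2, genome2)
  expect_equal(eff$codon_ref, "ATG")
  expect_equal(eff$codon_alt, "GTG")
  expect_equal(eff$aa_alt, "V")
  expect_equal(eff$effect, "nonsynonymous")
})

test_that("effect classification is strand-consistent under mirroring", {
  # same transcript sequence presented on plus and on minus strand
  tx <- "ATGGCCGAATAA" # Met Ala Glu Stop
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx)))
  pad <- function(s) paste0(paste(rep("C", 50), collapse = ""), s,
                            paste(rep("C", 50), collapse = ""))
  g_plus <- Biostrings::DNAStringSet(c(chr1 = pad(tx)))
  g_minus <- Biostrings::DNAStringSet(c(chr1 = pad(rc)))
  m_plus <- data.frame(gene_id = "g", transcript_id = "t", chrom = "chr1",
                       strand = "+", start = 51L, end = 62L, phase = 0L)
  m_minus <- data.frame(gene_id = "g", transcript_id = "t", chrom = "chr1",
                        strand = "-", start = 51L, end = 62L, phase = 0L)
  # substitute transcript position 5 (C -> T): GCC -> GTC, Ala -> Val
  eff_p <- classify_coding_effect("chr1", 55, "C", "T", m_plus, g_plus)
  # on the minus-strand genome, transcript position 5 sits at genome
  # coordinate 62 - 5 + 1 = 58 with complemented alleles
  eff_m <- classify_coding_effect("chr1", 58, "G", "A", m_minus, g_minus)
  expect_equal(eff_p$effect, eff_m$effect)
  expect_equal(eff_p$codon_alt, eff_m$codon_alt)
  expect_equal(eff_p$aa_alt, "V")
})

test_that("splice-junction codons are assembled across CDS segments", {
  # two CDS segments: 101..104 and 115..122 -> spliced ATGG|CCGAATAA
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    paste(rep("T", 100), collapse = ""), "ATGG", paste(rep("T", 10),
                                                       collapse = ""),
    "CCGAATAA", paste(rep("T", 78), collapse = ""))))
  models <- data.frame(gene_id = "g", transcript_id = "t", chrom = "chr1",
                       strand = "+", start = c(101L, 115L),
                       end = c(104L, 122L), phase = c(0L, NA))
  # spliced CDS = ATGGCCGAATAA; genome 104 (G) is codon 2 base 1 (GCC);
  # G -> A makes ACC: Ala -> Thr
  eff <- classify_coding_effect("chr1", 104, "G", "A", models, genome)
  expect_equal(eff$codon_ref, "GCC")
  expect_equal(eff$codon_alt, "ACC")
  expect_equal(eff$effect, "nonsynonymous")
})

test_that("CDS length not divisible by three is left unclassified", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(rep("A", 200),
                                                    collapse = "")))
  models <- data.frame(gene_id = "g", transcript_id = "t", chrom = "chr1",
                       strand = "+", start = 101L, end = 104L, phase = 0L)
  expect_warning(eff <- classify_coding_effect("chr1", 102, "A", "G",
                                               models, genome),
                 "multiple of 3")
  expect_equal(eff$effect, "unclassified")
})
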