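test_that("Hudson Fst matches the independent single-site oracle", {
  # popA: 5 diploids, alt count 2/10 (p = 0.2); popB: alt count 8/10
  calls <- rbind(matrix(c(1L, 1L, 0L, 0L, 0L), 5, 1),
                 matrix(c(2L, 2L, 2L, 1L, 1L), 5, 1))
  gm <- make_gm(calls, pos = 50)
  man <- population_manifest(gm$samples, rep(c("wild", "elite"), c(5, 5)))
  got <- window_fst(gm, win("chr1", 0, 100), man, "wild", "elite")
  expect_equal(got, 0.477124183006536, tolerance = 1e-12)

  # identical frequencies -> 0 in expectation of the numerator: use equal
  # allele counts in both groups
  calls2 <- rbind(matrix(c(0L, 1L, 2L, 1L, 0L), 5, 1),
                  matrix(c(0L, 1L, 2L, 1L, 0L), 5, 1))
  gm2 <- make_gm(calls2, pos = 50)
  got2 <- window_fst(gm2, win("chr1", 0, 100), man, "wild", "elite")
  expect_lt(got2, 0.05) # unbiased estimator fluctuates around 0
  # fixed difference -> 1 (finite-sample corrections vanish as n grows)
  big <- rbind(matrix(0L, 50, 1), matrix(2L, 50, 1))
  gm3 <- make_gm(big, pos = 50)
  man3 <- population_manifest(gm3$samples,
                              rep(c("wild", "elite"), c(50, 50)))
  expect_equal(window_fst(gm3, win("chr1", 0, 100), man3, "wild", "elite"),
               1, tolerance = 1e-12)
  # window with no usable site -> NA
  expect_true(is.na(window_fst(gm3, win("chr1", 1000, 2000), man3,
                               "wild", "elite")))
})

test_that("Weir-Cockerham variant is available and sane", {
  set.seed(8)
  gm <- random_gm(n = 20, s = 100, seed = 8)
  man <- make_manifest(gm, 10, 5)
  wc <- window_fst(gm, win("chr1", 0, 20000), man, "wild", "cultivated",
                   estimator = "wc")
  hd <- window_fst(gm, win("chr1", 0, 20000), man, "wild", "cultivated")
  expect_true(is.finite(wc) && is.finite(hd))
  expect_lt(abs(wc - hd), 0.15)
})

test_that("PBS follows the closed form and its symmetry", {
  expect_equal(pbs(0, 0, 0), 0)
  expect_equal(pbs(0.5, 0.5, 0), 0.6931471805599453, tolerance = 1e-12)
  # exchanging the two non-focal populations leaves PBS unchanged
  set.seed(2)
  f1 <- runif(50); f2 <- runif(50); f3 <- runif(50)
  expect_equal(pbs(f1, f2, f3), pbs(f2, f1, f3))
  # capping keeps the statistic finite
  expect_true(is.finite(pbs(1, 1, 1)))
})

test_that("diversity-reduction arithmetic reproduces the group percentages", {
  out <- diversity_reduction_summary(3.84e-3, 2.40e-3, 2.08e-3, 2.25e-3)
  expect_equal(round(out$retention_pct, 1), 58.6)
  expect_equal(round(out$domestication_reduction_pct, 1), 37.5)
  expect_equal(round(out$improvement_reduction_pct, 1), 8.3)
  # degenerate equalities
  same <- diversity_reduction_summary(1e-3, 1e-3, 1e-3, 1e-3)
  expect_equal(same$retention_pct, 100)
  expect_equal(same$domestication_reduction_pct, 0)
  expect_equal(same$improvement_reduction_pct, 0)
  # telescoping identity on random positive inputs
  set.seed(3)
  for (r in 1:10) {
    v <- sort(runif(3, 1e-4, 5e-3), decreasing = TRUE)
    out <- diversity_reduction_summary(v[1], v[2], v[3], mean(v[2:3]))
    expect_equal(out$domestication_reduction_pct +
                   out$improvement_reduction_pct,
                 100 * (v[1] - v[3]) / v[1])
  }
  expect_error(diversity_reduction_summary(0, 1, 1, 1), "positive")
})

test_that("merging selected windows unions overlapping and book-ended runs", {
  sel <- data.frame(chrom = "chr1",
                    start = c(0, 2000, 50000, 70000),
                    end = c(20000, 22000, 70000, 90000),
                    selected = TRUE, p_ratio = c(0.01, 0.02, 0.03, 0.005))
  reg <- merge_windows(sel, transition = "domestication")
  expect_equal(nrow(reg), 2)
  expect_equal(reg$start, c(0, 50000))
  expect_equal(reg$end, c(22000, 90000))
  expect_equal(reg$n_windows, c(2L, 2L))
  expect_equal(reg$min_p, c(0.01, 0.005))
  expect_equal(attr(reg, "total_mb"), (22000 + 40000) / 1e6)
  # far-apart windows stay separate
  sel2 <- data.frame(chrom = "chr1", start = c(0, 120000),
                     end = c(20000, 140000), selected = TRUE)
  expect_equal(nrow(merge_windows(sel2)), 2)
  # idempotence: merging merged regions changes nothing
  reg2 <- merge_windows(data.frame(chrom = reg$chrom, start = reg$start,
                                   end = reg$end, selected = TRUE))
  expect_equal(reg2$start, reg$start)
  expect_equal(reg2$end, reg$end)
})

test_that("merged regions equal the sort-and-sweep interval union oracle", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 30
    starts <- sort(sample(0:100, n, replace = TRUE)) * 1000
    sel <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                      start = starts, end = starts + 20000, selected = TRUE)
    sel <- sel[order(sel$chrom, sel$start), ]
    got <- merge_windows(sel)
    # oracle: linear sweep over sorted intervals per chromosome
    oracle <- list()
    for (ch in sort(unique(sel$chrom))) {
      s <- sel[sel$chrom == ch, ]
      cur_s <- s$start[1]; cur_e <- s$end[1]
      for (k in seq_len(nrow(s))[-1]) {
        if (s$start[k] <= cur_e) cur_e <- max(cur_e, s$end[k])
        else {
          oracle[[length(oracle) + 1]] <- c(cur_s, cur_e)
          cur_s <- s$start[k]; cur_e <- s$end[k]
        }
      }
      oracle[[length(oracle) + 1]] <- c(cur_s, cur_e)
    }
    om <- do.call(rbind, oracle)
    expect_equal(got$start, om[, 1])
    expect_equal(got$end, om[, 2])
  }
})

test_that("domestication scan recovers an injected sweep", {
  sw <- data.frame(chrom = "chr1", start = 200000, end = 240000,
                   transition = "domestication")
  sim <- simulate_populations(test_sim_config(chrom_length = 6e5,
                                              sweep_specs = sw, seed = 7))
  windows <- sliding_windows(c(chr1 = 6e5))
  scan <- domestication_scan(sim$genotypes, sim$manifest, windows)
  regions <- merge_windows(scan)
  hit <- any(regions$start < 240000 & regions$end > 200000)
  expect_true(hit)
  # the genome-minimum log ratio lies inside the sweep
  j <- which.min(scan$log_ratio)
  expect_true(scan$start[j] < 240000 && scan$end[j] > 200000)
  expect_equal(attr(scan, "alpha"), 0.05)
})

test_that("improvement scan recovers an injected elite sweep at the PBS maximum", {
  sw <- data.frame(chrom = "chr1", start = 300000, end = 340000,
                   transition = "improvement")
  sim <- simulate_populations(test_sim_config(chrom_length = 8e5,
                                              sweep_specs = sw, seed = 11))
  windows <- sliding_windows(c(chr1 = 8e5))
  scan <- improvement_scan(sim$genotypes, sim$manifest, windows)
  j <- which.max(scan$pbs_elite)
  expect_true(scan$start[j] < 340000 && scan$end[j] > 300000)
  regions <- merge_windows(scan)
  expect_true(any(regions$start < 340000 & regions$end > 300000))
  expect_equal(attr(scan, "alpha_corrected"), 0.001)
  # undefined-PBS windows are never selected
  expect_false(any(scan$selected & !is.finite(scan$pbs_elite)))
})

test_that("sample exclusion drops accessions before grouping", {
  sim <- simulate_populations(test_sim_config(chrom_length = 2e5, seed = 5))
  windows <- sliding_windows(c(chr1 = 2e5))
  drop2 <- population_samples(sim$manifest, "cultivated")[1:2]
  s1 <- domestication_scan(sim$genotypes, sim$manifest, windows)
  s2 <- domestication_scan(sim$genotypes, sim$manifest, windows,
                           exclude = drop2)
  expect_false(identical(s1$pi_cultivated, s2$pi_cultivated))
})

test_that("scans refuse degenerate window sets", {
  sim <- simulate_populations(test_sim_config(chrom_length = 5e4, seed = 5))
  few <- sliding_windows(c(chr1 = 5e4))[1:10, ]
  expect_error(domestication_scan(sim$genotypes, sim$manifest, few),
               "50 windows")
  expect_error(improvement_scan(sim$genotypes, sim$manifest, few),
               "50 windows")
})
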