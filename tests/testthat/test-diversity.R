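test_that("sliding windows tile chromosomes per the counting oracle", {
  w <- sliding_windows(c(chr1 = 40000))
  expect_equal(nrow(w), floor((40000 - 20000) / 2000) + 1) # 11
  expect_equal(w$start[1], 0)
  expect_equal(w$end[1], 20000)
  expect_equal(w$start[nrow(w)], 20000)
  expect_equal(w$end[nrow(w)], 40000)
  # chromosome exactly one window long
  expect_equal(nrow(sliding_windows(c(chr1 = 20000))), 1)
  # short chromosome collapses to one whole-chromosome window, logged
  expect_message(w2 <- sliding_windows(c(chr1 = 1500)), "shorter")
  expect_equal(w2$end - w2$start, 1500)
  expect_error(sliding_windows(c(chr1 = 1e5), window = 10, step = 20))
})

test_that("theta-pi matches enumeration of haplotype pairs", {
  # one site, 4 haplotypes, alt count 2, span 100:
  # 4 differing pairs / 6 pairs / 100 bp
  gm <- make_gm(matrix(c(1L, 1L), 2, 1), pos = 50)
  expect_equal(theta_pi(gm, win("chr1", 0, 100)), 4 / 6 / 100,
               tolerance = 1e-12)
  expect_equal(theta_pi(gm, win("chr1", 0, 100)), 0.006667,
               tolerance = 1e-4)
  # window with no segregating sites
  gm0 <- make_gm(matrix(0L, 3, 2))
  expect_equal(theta_pi(gm0, win("chr1", 0, 1000)), 0)
  # random windows against the all-pairs oracle
  for (seed in 1:3) {
    gmr <- random_gm(n = 10, s = 40, miss = 0.15, seed = seed)
    wdw <- win("chr1", 0, 5000)
    expect_equal(theta_pi(gmr, wdw), brute_theta_pi(gmr, wdw),
                 tolerance = 1e-12)
  }
})

test_that("Watterson's estimator uses the harmonic correction", {
  # S = 3, n = 4 haplotypes, span 100 -> 3 / (11/6 * 100)
  gm <- make_gm(matrix(c(0L, 1L, 1L, 0L, 2L, 1L), 2, 3), pos = c(10, 20, 30))
  expect_equal(theta_w(gm, win("chr1", 0, 100)), 0.0163636363636,
               tolerance = 1e-10)
  gm0 <- make_gm(matrix(0L, 3, 2))
  expect_equal(theta_w(gm0, win("chr1", 0, 100)), 0)
})

test_that("theta-pi and theta-w agree in expectation under neutrality", {
  pi_hat <- w_hat <- numeric(20)
  for (seed in 1:20) {
    sim <- simulate_populations(test_sim_config(chrom_length = 2e5,
                                                seed = 300 + seed))
    wild <- subset_population(sim$genotypes, sim$manifest, "wild")
    wdw <- win("chr1", 0, 2e5)
    pi_hat[seed] <- theta_pi(wild, wdw)
    w_hat[seed] <- theta_w(wild, wdw)
  }
  expect_lt(abs(mean(pi_hat) / mean(w_hat) - 1), 0.10)
})

test_that("Tajima's D matches the independent constants oracle", {
  # n = 10 haplotypes (5 diploids), S = 5, alt counts 1,3,5,2,7;
  # expected value computed independently from the 1989 constants
  calls <- cbind(c(1L, 0L, 0L, 0L, 0L),
                 c(2L, 1L, 0L, 0L, 0L),
                 c(2L, 2L, 1L, 0L, 0L),
                 c(1L, 1L, 0L, 0L, 0L),
                 c(2L, 2L, 2L, 1L, 0L))
  gm <- make_gm(calls, pos = c(10, 20, 30, 40, 50))
  expect_equal(tajimas_d(gm, win("chr1", 0, 100)), 0.628476237735245,
               tolerance = 1e-10)
  # S = 0 -> undefined
  gm0 <- make_gm(matrix(2L, 5, 1))
  expect_true(is.na(tajimas_d(gm0, win("chr1", 0, 100))))
  # D = 0 whenever window totals pi and S/a1 coincide: with S = 1 and
  # n = 4, pi = a1^{-1} requires 2c(n-c)/(n(n-1)) = 1/a1; engineered check
  # via the window_diversity totals instead
  wd <- window_diversity(gm, win("chr1", 0, 100))
  k <- divsweep:::tajima_constants(10)
  expect_equal(wd$tajima_d,
               (wd$pi_total - wd$n_segregating / k$a1) /
                 sqrt(k$e1 * wd$n_segregating +
                        k$e2 * wd$n_segregating * (wd$n_segregating - 1)))
})

test_that("windowed and single-window statistics agree on simulated data", {
  sim <- simulate_populations(test_sim_config(chrom_length = 1e5, seed = 9))
  wild <- subset_population(sim$genotypes, sim$manifest, "wild")
  windows <- sliding_windows(c(chr1 = 1e5))
  wd <- window_diversity(wild, windows)
  for (k in c(1, 17, nrow(windows))) {
    expect_equal(wd$theta_pi[k], theta_pi(wild, windows[k, ]))
    expect_equal(wd$theta_pi[k], brute_theta_pi(wild, windows[k, ]),
                 tolerance = 1e-12)
    expect_equal(wd$tajima_d[k], tajimas_d(wild, windows[k, ]))
  }
})

test_that("SNV accumulation matches exhaustive enumeration and saturates", {
  # 3 accessions carrying alt alleles at site sets {1,2}, {2,3}, {3,4}
  calls <- rbind(c(1L, 1L, 0L, 0L),
                 c(0L, 1L, 1L, 0L),
                 c(0L, 0L, 1L, 1L))
  gm <- make_gm(calls)
  man <- population_manifest(gm$samples, rep("wild", 3))
  curve <- snv_accumulation(gm, man, "wild", k_values = c(1, 2, 3),
                            exhaustive = TRUE, seed = 1)
  expect_equal(curve$mean[curve$k == 2], 10 / 3, tolerance = 1e-12)
  # k = group size: exact total, zero variance, seed-independent
  expect_equal(curve$mean[curve$k == 3], 4)
  expect_equal(curve$sd[curve$k == 3], 0)
  c2 <- snv_accumulation(gm, man, "wild", 3, seed = 99)
  expect_equal(c2$mean, 4)
  # monotone non-decreasing means for any seed
  gmr <- random_gm(n = 8, s = 60, seed = 13)
  manr <- population_manifest(gmr$samples, rep("wild", 8))
  for (seed in 1:3) {
    cv <- snv_accumulation(gmr, manr, "wild", 1:8, reps = 30, seed = seed)
    expect_true(all(diff(cv$mean) >= 0))
  }
  expect_error(snv_accumulation(gm, man, "wild", 5), "group size")
})

test_that("site frequency spectrum conserves counts and matches neutrality", {
  gm <- make_gm(rbind(c(2L), c(1L), c(0L), c(0L), c(0L))) # alt count 3/10
  spec <- sfs(gm)
  expect_equal(spec$n_sites[spec$count == 3], 1)
  expect_equal(sum(spec$n_sites), 1)
  # folded spectrum bins by minor allele
  gm2 <- make_gm(matrix(2L, 3, 1)) # alt count 6/6 -> folded 0
  spec2 <- sfs(gm2, folded = TRUE)
  expect_equal(spec2$n_sites[spec2$count == 0], 1)
  # conservation on random data
  gmr <- random_gm(n = 10, s = 200, miss = 0.05, seed = 21)
  expect_equal(sum(sfs(gmr)$n_sites), 200)

  # neutral generator: the wild sample spectrum follows the 1/i standing
  # spectrum pushed through Hardy-Weinberg genotype sampling. Expected bin
  # probabilities computed independently as the binomial mixture
  # P(j) ~ sum_i (1/i) Binom(j | n_hap, i/n_hap), j = 1..n_hap-1.
  sim <- simulate_populations(test_sim_config(chrom_length = 6e5,
                                              seed = 31))
  wild <- subset_population(sim$genotypes, sim$manifest, "wild")
  spec3 <- sfs(wild)
  n_hap <- 2 * n_samples(wild)
  seg <- spec3$count >= 1 & spec3$count <= n_hap - 1
  obs <- spec3$n_sites[seg]
  i <- 1:(n_hap - 1)
  expected_p <- vapply(i, function(j)
    sum((1 / i) * dbinom(j, n_hap, i / n_hap)), numeric(1))
  expected_p <- expected_p / sum(expected_p)
  fit <- suppressWarnings(chisq.test(obs, p = expected_p,
                                     simulate.p.value = TRUE, B = 2000))
  expect_gt(fit$p.value, 0.01)
})
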