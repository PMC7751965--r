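test_that("the TSS landscape hits the close-pair fraction by construction", {
  cfg0 <- sim_config(seed = 1, n_tss = 500, close_pair_fraction = 0)
  tt0 <- generate_tss_landscape(cfg0)
  d0 <- diff(sort(tt0$position))
  expect_true(all(d0 >= 100))

  cfg <- sim_config(seed = 1, n_tss = 2000, close_pair_fraction = 0.556)
  tt <- generate_tss_landscape(cfg)
  pos <- sort(tt$position)
  gaps <- diff(pos)
  close <- c(gaps < 100, FALSE) | c(FALSE, gaps < 100)
  expect_lt(abs(mean(close) - 0.556), 0.02)

  expect_identical(generate_tss_landscape(cfg)$position, tt$position)
  expect_error(generate_tss_landscape(sim_config(n_tss = 1000,
                                                 chrom_length = 10000)),
               "too short")
})

test_that("binding propensities are realized in the features", {
  # propensity 1 in one window -> that binary feature is 1 everywhere
  prop <- matrix(0, 2, 8)
  prop[1, 6] <- 1  # TF001, window [1, 100]
  cfg <- sim_config(seed = 2, n_tss = 200, m_tfs = 2,
                    binding_propensity = prop, close_pair_fraction = 0)
  tt <- generate_tss_landscape(cfg)
  tfbrs <- generate_tfbr_sets(tt, cfg)
  fm <- build_primary_features(tt, tfbrs)
  expect_true(all(fm$values[, "TF001 [1, 100]"] == 1))
  # propensity 0 and no background -> the other TF has no intervals
  expect_equal(nrow(tfbrs$TF002$intervals), 0)
  expect_true(all(fm$values[, fm$columns$tf %in% "TF002"] == 0))

  # empirical binding fraction within 3 binomial SEs of the propensity
  cfg3 <- sim_config(seed = 3, n_tss = 5000, m_tfs = 1,
                     binding_propensity = 0.3, close_pair_fraction = 0)
  tt3 <- generate_tss_landscape(cfg3)
  fm3 <- build_primary_features(tt3, generate_tfbr_sets(tt3, cfg3))
  frac <- mean(fm3$values[, fm3$columns$kind == "binary"])
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / (5000 * 8)))
})

test_that("activities realize the stated linear LTE model", {
  # no features, no noise -> LTE is exactly the intercept
  cfg <- sim_config(seed = 4, n_tss = 100, m_tfs = 2, noise_sd = 0,
                    binding_propensity = 0, intercept = 1.5,
                    true_effects = data.frame(tf = "TF001", window = 6,
                                              beta = 0.5))
  ds <- simulate_dataset(cfg)
  expect_equal(unname(lte_transform(ds$tss$SIM)), rep(1.5, 100))

  # noiseless identifiability: selection recovers effects and coefficients
  cfg2 <- sim_config(seed = 5, n_tss = 1500, m_tfs = 10, noise_sd = 0,
                     intercept = 1.5)
  ds2 <- simulate_dataset(cfg2)
  y <- lte_transform(ds2$tss$SIM)
  m <- forward_select(ds2$features, y,
                      selection_config(max_steps = 12))
  tr <- ds2$truth$beta
  expect_true(all(names(tr) %in% m$features))
  expect_equal(unname(m$coefficients[names(tr)]), unname(tr),
               tolerance = 1e-8)
  expect_equal(m$intercept, 1.5, tolerance = 1e-8)

  # with noise, OLS on the true support recovers coefficients within 3 SE
  cfg3 <- sim_config(seed = 6, n_tss = 5000, m_tfs = 10, noise_sd = 0.3,
                     intercept = 1.5)
  ds3 <- simulate_dataset(cfg3)
  m3 <- ols_fit(ds3$features$values[, names(ds3$truth$beta)],
                lte_transform(ds3$tss$SIM))
  z <- (m3$coefficients - ds3$truth$beta) / m3$se
  expect_true(all(abs(z) < 3))
})

test_that("caller replicates reproduce peaks and inject true orphans", {
  true_cfg <- sim_config(seed = 7, n_tss = 150, m_tfs = 1,
                         close_pair_fraction = 0)
  tt <- generate_tss_landscape(true_cfg)
  peaks <- generate_tfbr_sets(tt, true_cfg)[[1]]
  peaks$experiment_id <- "exp1"

  clean_cfg <- sim_config(seed = 8, jitter_sd = 0, dropout = 0,
                          orphan_rate = 0)
  reps <- generate_caller_replicates(peaks, clean_cfg)
  cl <- cluster_caller_peaks(reps)
  expect_length(cl, nrow(peaks$intervals))
  expect_true(all(vapply(cl, `[[`, 0L, "support") == 4L))

  orph_cfg <- sim_config(seed = 9, jitter_sd = 0, dropout = 0,
                         orphan_rate = 0.2)
  reps2 <- generate_caller_replicates(peaks, orph_cfg)
  cl2 <- cluster_caller_peaks(reps2)
  n_false <- 4 * round(0.2 * nrow(peaks$intervals))
  expect_equal(sum(vapply(cl2, `[[`, 0L, "support") == 1L), n_false)

  # the FPCM gate at 3.5 recovers exactly the true peak set
  recovered <- refine_with_fpcm_gate(cl2, fpcm = 3.5)
  expect_equal(recovered$intervals, peaks$intervals)
  # and at 2.5 keeps the orphans
  kept <- refine_with_fpcm_gate(cl2, fpcm = 2.5)
  expect_equal(nrow(kept$intervals), length(cl2))
})

test_that("multi-line simulation shares effects with divergent binding", {
  cfg <- sim_config(seed = 10, n_tss = 800, m_tfs = 8,
                    line_divergence = 0.2)
  ml <- simulate_multi_line(cfg, n_lines = 3)
  expect_length(ml$lines, 3)
  ys <- vapply(ml$lines, `[[`, numeric(800), "y")
  # lines correlate strongly but are not identical
  cc <- cor(ys)[lower.tri(matrix(0, 3, 3))]
  expect_true(all(cc > 0.3 & cc < 0.999))
  b1 <- vapply(ml$lines, function(l) l$truth$beta[[1]], 0)
  expect_equal(b1, rep(b1[1], 3), ignore_attr = TRUE)
})
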