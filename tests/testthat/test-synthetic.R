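test_that("decay generator is exact at zero noise and seed-reproducible", {
  d <- c(0, 0.4, 1.4, 2.4, 3.6)
  s0 <- gen_decay_series(1.5, 1e5, d, noise_fraction = 0, seed = 1)
  expect_equal(s0$intensities, 1e5 * exp(-1.5 * d))
  s1 <- gen_decay_series(1.5, 1e5, d, noise_fraction = 0.02, seed = 42)
  s2 <- gen_decay_series(1.5, 1e5, d, noise_fraction = 0.02, seed = 42)
  expect_identical(s1$intensities, s2$intensities)
  expect_false(identical(
    s1$intensities,
    gen_decay_series(1.5, 1e5, d, noise_fraction = 0.02, seed = 43)$intensities))
  expect_error(gen_decay_series(1.5, 1e5, d, noise_fraction = -0.1))
})

test_that("decay noise has the requested spread (law of large numbers)", {
  s <- gen_decay_series(0, 1e5, delays = rep(0, 10000),
                        noise_fraction = 0.05, seed = 9)
  expect_equal(sd(s$intensities), 0.05 * 1e5, tolerance = 0.03)
})

test_that("NOE pair generator round-trips and its errors calibrate", {
  p0 <- gen_noe_pair(0.43, 1e5, noise_fraction = 0, seed = 1)
  expect_equal(compute_noe(p0$sat, p0$ref)$noe, 0.43)

  p1 <- gen_noe_pair(1, 1e5, noise_fraction = 0.001, seed = 2)
  expect_equal(p1$sat$height / p1$ref$height, 1, tolerance = 0.01)

  # 95%-interval coverage of the propagated error over many seeds
  hits <- vapply(1:300, function(sd_) {
    p <- gen_noe_pair(0.43, 1e5, noise_fraction = 0.02, seed = sd_)
    r <- compute_noe(p$sat, p$ref)
    abs(r$noe - 0.43) <= 1.96 * r$noe_error
  }, logical(1))
  expect_gt(mean(hits), 0.90)
  expect_lte(mean(hits), 1)
})

test_that("dispersion generator round-trips through R2,eff at zero noise", {
  g <- cpmg_grid("Na_MQ")
  st <- list(cpmg_settings(g$T_relax, g$nu_cpmg, 800, "MQ_13C"))
  p <- exchange_params(390, 0.05, dw_C = 1.5, dw_H = 0.04, r2_0 = 20)
  d <- gen_dispersion_dataset(p, st, noise_fraction = 0, seed = 1)[[1]]
  cv <- r2eff_from_intensities(d$I, d$I0, d$settings)
  model <- mq_model_r2eff(p, within <- local({
    s <- d$settings; s$nu_cpmg <- cv$nu; s
  }))
  expect_equal(cv$r2eff, model, tolerance = 1e-10)
})

test_that("cluster generator volumes track populations (quadrature oracle)", {
  pos <- rbind(c(0.12, 23.4), c(0.48, 24.6))
  lw <- rbind(c(0.012, 0.12), c(0.012, 0.12))
  g <- gen_peak_cluster(pos, lw, c(0.7, 0.3),
                        list(x = seq(-0.4, 1.0, length.out = 201),
                             y = seq(21.5, 26.5, length.out = 151)),
                        noise_fraction = 0, seed = 1)
  v <- grid_volume_split(g, pos[, 1])
  expect_equal(v[1] / sum(v), 0.7, tolerance = 0.01)

  # single state: maximum at the peak, unimodal along both axes
  g1 <- gen_peak_cluster(matrix(c(0.3, 24), 1), matrix(c(0.02, 0.2), 1), 1,
                         list(x = seq(0, 0.6, length.out = 61),
                              y = seq(23, 25, length.out = 41)),
                         noise_fraction = 0, seed = 1)
  ij <- which(g1$z == max(g1$z), arr.ind = TRUE)
  expect_equal(g1$x[ij[1]], 0.3, tolerance = 0.01)
  expect_equal(g1$y[ij[2]], 24.0, tolerance = 0.05)

  # reproducibility under a fixed seed
  pr <- spinflex_preset("L48a_K")
  a <- gen_peak_cluster(pr$positions, pr$linewidths, pr$populations,
                        pr$grid, pr$noise_fraction, seed = 7)
  b <- gen_peak_cluster(pr$positions, pr$linewidths, pr$populations,
                        pr$grid, pr$noise_fraction, seed = 7)
  expect_identical(a$z, b$z)
})

test_that("CSP table generator plants a recoverable perturbed set", {
  # zero effects + zero noise: all CSPs are exactly zero
  t0 <- gen_csp_tables(12, noise_ppm = 0, seed = 1)
  tab0 <- csp_table(t0$cond1, t0$cond2)
  expect_true(all(tab0$csp == 0))

  # noise-free construction: the threshold rule recovers exactly the
  # planted set (the trimmed mean and SD of the null values are zero)
  planted <- data.frame(residue = c(4, 17, 23),
                        d_H = c(0.25, 0.30, 0.20),
                        d_X = c(2.0, 2.5, 1.8))
  tt <- gen_csp_tables(40, planted, noise_ppm = 0, seed = 6)
  tab <- csp_table(tt$cond1, tt$cond2)
  expect_setequal(tab$residue_id[which(tab$significant)], planted$residue)

  # with realistic noise every planted residue is still detected (the
  # 1.5-sigma rule trades false positives for sensitivity)
  tt <- gen_csp_tables(40, planted, noise_ppm = 0.002, seed = 6)
  tab <- csp_table(tt$cond1, tt$cond2)
  expect_true(all(planted$residue %in% tab$residue_id[which(tab$significant)]))
})

test_that("null CSP tables trip the threshold at its nominal tail mass", {
  # empirical false-positive rate over replicate null tables ...
  n_res <- 30
  fp <- vapply(1:250, function(sd_) {
    tt <- gen_csp_tables(n_res, noise_ppm = 0.004, seed = sd_)
    tab <- csp_table(tt$cond1, tt$cond2)
    mean(tab$significant)
  }, numeric(1))
  # ... compared with the rule's tail mass on one very large null sample
  set.seed(1)
  big <- sqrt(rnorm(2e5, 0, 1)^2 + rnorm(2e5, 0, 0.101)^2)  # H + weighted N
  thr <- significance_threshold(big, 0.1, 1.5)
  p_nominal <- mean(big > thr$threshold)
  expect_lt(abs(mean(fp) - p_nominal), 0.04)
})

test_that("presets are immutable and carry their assumptions", {
  a <- spinflex_preset("nak_na_sf")
  b <- spinflex_preset("nak_na_sf")
  expect_identical(a, b)
  expect_equal(a$kex, 390)
  expect_match(a$assumed$note, "assumption")
  expect_equal(spinflex_preset("nak_na_sf_sq")$kex, 356)
  expect_equal(sum(spinflex_preset("L48a_K")$populations), 1)
  expect_equal(spinflex_preset("L48a_Na")$populations, c(0.47, 0.37, 0.16))
  expect_equal(spinflex_preset("N68_K")$noe_true, 0.43)
})
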