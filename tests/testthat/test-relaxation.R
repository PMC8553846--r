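five_delays <- c(0, 0.4, 1.4, 2.4, 3.6)

test_that("exponential fit recovers noiseless model parameters exactly", {
  # constant series: zero rate
  s <- relax_series(1L, "R1", five_delays, rep(100, 5), rep(2, 5))
  f <- fit_exponential(s)
  expect_true(f$converged)
  expect_equal(f$rate, 0, tolerance = 1e-8)
  expect_equal(f$amplitude, 100, tolerance = 1e-8)

  # exact model recovery
  s <- relax_series(1L, "R1", five_delays, 50 * exp(-2 * five_delays),
                    rep(0.5, 5))
  f <- fit_exponential(s)
  expect_lt(abs(f$rate - 2) / 2, 1e-6)
  expect_lt(abs(f$amplitude - 50) / 50, 1e-6)

  # two-point closed form: R = log(I1/I2) / (t2 - t1)
  s <- relax_series(1L, "R1", c(0, 1), c(80, 80 / exp(1)), c(1, 1))
  expect_equal(fit_exponential(s)$rate, 1, tolerance = 1e-8)
})

test_that("noiseless recovery holds across the physiological rate range", {
  for (R in c(0.1, 0.7, 2, 5, 20)) for (I0 in c(1, 1e5)) {
    y <- I0 * exp(-R * five_delays)
    s <- relax_series(1L, "R1", five_delays, y, pmax(0.02 * y, 1e-9))
    f <- fit_exponential(s)
    expect_lt(abs(f$rate - R) / R, 1e-6)
    expect_lt(abs(f$amplitude - I0) / I0, 1e-6)
  }
})

test_that("series with fewer than two distinct delays are rejected as unfittable", {
  s <- relax_series(1L, "R1", c(1, 1), c(50, 51), c(1, 1))
  expect_false(s$fittable)
  expect_error(fit_exponential(s), "not fittable")
})

test_that("Monte Carlo errors are reproducible and track the noise level", {
  s <- gen_decay_series(1.5, 1e5, five_delays, noise_fraction = 0.02,
                        seed = 11)
  f <- fit_exponential(s)
  e1 <- monte_carlo_error(s, f, n_mc = 300, seed = 5)
  e2 <- monte_carlo_error(s, f, n_mc = 300, seed = 5)
  expect_identical(e1$rate_error, e2$rate_error)
  expect_identical(e1$amplitude_error, e2$amplitude_error)
  expect_gt(e1$rate_error, 0)

  # errors shrink toward zero with the noise level ...
  tiny <- s
  tiny$intensities <- 1e5 * exp(-1.5 * five_delays)
  tiny$intensity_errors <- rep(1e-4 * 1e5, 5) * 1e-3
  ft <- fit_exponential(tiny)
  et <- monte_carlo_error(tiny, ft, n_mc = 300, seed = 5)
  expect_lt(et$rate_error, 1e-3)

  # ... and scale roughly linearly with it in the small-noise regime
  dbl <- s
  dbl$intensity_errors <- 2 * s$intensity_errors
  ed <- monte_carlo_error(s, f, n_mc = 400, seed = 9)
  e2x <- monte_carlo_error(dbl, f, n_mc = 400, seed = 9)
  expect_equal(e2x$rate_error / ed$rate_error, 2, tolerance = 0.25)
})

test_that("R1rho converts to R2 with the offset correction", {
  r1rho <- list(residue_id = 1L, rate = 10, rate_error = 0.4)
  r1 <- list(residue_id = 1L, rate = 1, rate_error = 0.05)

  # on resonance theta = 90 deg: R2 equals R1rho exactly
  on <- r1rho_to_r2(r1rho, r1, spinlock_settings(1923, 0))
  expect_equal(on$r2, 10)
  expect_equal(on$r2_error, 0.4)

  # theta = 45 deg: R2 = 2 R1rho - R1
  mid <- r1rho_to_r2(r1rho, r1, spinlock_settings(1923, 1923))
  expect_equal(mid$theta, 45)
  expect_equal(mid$r2, 19, tolerance = 1e-12)

  # continuity: small offset stays near the on-resonance value
  near <- r1rho_to_r2(r1rho, r1, spinlock_settings(1923, 5))
  expect_equal(near$r2, 10, tolerance = 1e-4)
})

test_that("propagated R2 error matches Monte Carlo sampling", {
  sl <- spinlock_settings(1923, 1200)
  r1rho <- list(residue_id = 1L, rate = 12, rate_error = 0.5)
  r1 <- list(residue_id = 1L, rate = 1.2, rate_error = 0.08)
  prop <- r1rho_to_r2(r1rho, r1, sl)
  set.seed(21)
  draws <- vapply(seq_len(20000), function(i) {
    a <- list(residue_id = 1L, rate = rnorm(1, 12, 0.5), rate_error = 0.5)
    b <- list(residue_id = 1L, rate = rnorm(1, 1.2, 0.08), rate_error = 0.08)
    r1rho_to_r2(a, b, sl)$r2
  }, numeric(1))
  expect_equal(prop$r2_error, sd(draws), tolerance = 0.05)
})

test_that("NOE ratio and propagated error follow the closed form", {
  mk <- function(h, e, res = 68L) data.frame(residue_id = res,
                                             height = h, height_error = e)
  r <- compute_noe(mk(100, 2), mk(100, 2))
  expect_equal(r$noe, 1)
  expect_equal(r$noe_error, sqrt(2) * 0.02, tolerance = 1e-12)

  r <- compute_noe(mk(43, 2), mk(100, 2))
  expect_equal(r$noe, 0.43)
  expect_equal(r$noe_error, 0.43 * sqrt((2 / 43)^2 + (2 / 100)^2),
               tolerance = 1e-12)
  expect_equal(r$noe_error, 0.022, tolerance = 0.02)

  # identity: any peak against itself gives exactly 1
  p <- mk(-512.3, 11)
  expect_equal(compute_noe(p, p)$noe, 1)

  # zero saturated intensity is a valid (fully mobile) result
  r0 <- compute_noe(mk(0, 2), mk(100, 2))
  expect_equal(r0$noe, 0)
  expect_equal(r0$noe_error, 0.02)

  expect_error(compute_noe(mk(50, 2), mk(0, 2)), "zero")
})

test_that("helical-baseline flags isolate constructed dynamic residues", {
  helix <- list(c(1, 10), c(21, 30))
  res <- data.frame(residue_id = 1:35,
                    r1 = rep(1.0, 35), noe = rep(0.8, 35))
  set.seed(3)
  res$r1[c(1:10, 21:30)] <- rnorm(20, 1.0, 0.02)
  res$noe[c(1:10, 21:30)] <- rnorm(20, 0.80, 0.01)
  base <- baseline_and_flags(res, helix)
  loop <- 11:15
  res2 <- res
  res2$r1[loop] <- base$r1_baseline[1] + 5 * base$r1_sd[1]
  res2$noe[loop] <- base$noe_baseline[1] - 5 * base$noe_sd[1]
  flagged <- baseline_and_flags(res2, helix)
  expect_identical(which(flagged$flag_dynamic), loop)

  # shift invariance: adding a constant to all R1 changes nothing
  res3 <- res2
  res3$r1 <- res3$r1 + 7.5
  expect_identical(baseline_and_flags(res3, helix)$flag_dynamic,
                   flagged$flag_dynamic)

  # identical values: no flags
  resx <- data.frame(residue_id = 1:35, r1 = 1, noe = 0.8)
  expect_false(any(baseline_and_flags(resx, helix)$flag_dynamic))

  expect_error(baseline_and_flags(res, list()), "annotation")
})
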