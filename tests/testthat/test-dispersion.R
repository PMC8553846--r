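test_that("settings enforce the even-pulse-count CPMG convention", {
  s <- cpmg_settings(0.02, c(50, 100, 1000), 800, "MQ_13C")
  expect_s3_class(s, "cpmg_settings")
  # every shipped grid satisfies the constraint at its T_relax
  for (g in c("K_MQ", "Na_MQ", "Na_SQ")) {
    gr <- cpmg_grid(g)
    expect_no_error(cpmg_settings(gr$T_relax, gr$nu_cpmg, 800, "SQ_1H"))
  }
  expect_error(cpmg_settings(0.02, 75, 800), "even integer")
  expect_error(cpmg_settings(0.03, 75, 800), "even integer")
})

test_that("R2,eff from intensities follows the log-ratio closed form", {
  s <- cpmg_settings(0.02, c(50, 100, 200, 400, 1000), 800, "MQ_13C")
  # flat: I = I0 everywhere
  cv <- r2eff_from_intensities(rep(500, 5), 500, s)
  expect_equal(cv$r2eff, rep(0, 5))
  # closed form: I/I0 = exp(-0.3), T = 20 ms -> 15 s^-1
  cv <- r2eff_from_intensities(rep(1000 * exp(-0.3), 5), 1000, s)
  expect_equal(cv$r2eff, rep(15, 5), tolerance = 1e-12)
})

test_that("replicate nu points pool to mean and replicate SD", {
  s <- cpmg_settings(0.02, c(50, 200, 200, 1000), 800, "MQ_13C")
  I <- 1000 * exp(-0.02 * c(10, 14, 16, 8))
  cv <- r2eff_from_intensities(I, 1000, s)
  i200 <- which(cv$nu == 200)
  expect_equal(cv$r2eff[i200], 15.0, tolerance = 1e-9)
  expect_equal(cv$r2eff_error[i200], sd(c(14, 16)), tolerance = 1e-9)
  # non-replicated points inherit the pooled replicate SD
  expect_equal(cv$r2eff_error[cv$nu == 50], sd(c(14, 16)),
               tolerance = 1e-9)

  # replicate SDs below the intensity-noise floor are raised to it
  # (floor = fallback_noise / T_relax, here 0.02 / 0.02 s = 1 s^-1)
  I2 <- 1000 * exp(-0.02 * c(10, 14.9, 15.1, 8))
  cv3 <- r2eff_from_intensities(I2, 1000, s)
  expect_equal(cv3$r2eff[cv3$nu == 200], 15.0, tolerance = 1e-9)
  expect_equal(unique(cv3$r2eff_error), 1.0, tolerance = 1e-9)

  # non-positive intensities are dropped, not propagated
  expect_warning(
    cv2 <- r2eff_from_intensities(c(I[1:3], -5), 1000, s), "dropped")
  expect_length(cv2$nu, 2)
})

test_that("Rex endpoint estimate equals the direct subtraction", {
  s <- cpmg_settings(0.03, cpmg_grid("Na_MQ")$nu_cpmg, 800, "MQ_13C")
  p <- exchange_params(390, 0.05, dw_C = 1.5, dw_H = 0.04, r2_0 = 20)
  r2 <- mq_model_r2eff(p, s)
  cv <- r2eff_from_intensities(1e6 * exp(-r2 * 0.03), 1e6, s)
  rx <- rex_estimate(cv)
  expect_equal(rx$rex,
               cv$r2eff[which.min(cv$nu)] - cv$r2eff[which.max(cv$nu)])
  expect_gt(rx$rex, 10)  # strong exchange for the V64-like probe
  expect_equal(rx$nu_low, 33.33)
  expect_equal(rx$nu_high, 1000)
  expect_match(rx$note, "underestimated")

  # flat curve gives zero
  cvf <- r2eff_from_intensities(rep(100, length(s$nu_cpmg)), 100, s)
  expect_equal(rex_estimate(cvf)$rex, 0)
})

test_that("MQ model matches an independent fine-step integrator", {
  s <- cpmg_settings(0.02, c(50, 100, 250, 1000), 800, "MQ_13C")
  for (kex in c(200, 800)) for (p_b in c(0.03, 0.1)) {
    p <- exchange_params(kex, p_b, dw_C = 1.5, dw_H = 0.04, r2_0 = 5)
    mod <- mq_model_r2eff(p, s)
    orc <- vapply(s$nu_cpmg, oracle_mq_r2eff, numeric(1),
                  T_relax = 0.02, kex = kex, p_b = p_b,
                  dwH_rad = ppm_to_rad(0.04, 800, "H"),
                  dwC_rad = ppm_to_rad(1.5, 800, "C")) + 5
    expect_lt(max(abs(mod - orc)), 0.05)
  }
})

test_that("SQ model matches the integrator and its closed-form limits", {
  s <- cpmg_settings(0.02, c(50, 100, 250, 1000), 800, "SQ_1H")
  for (kex in c(200, 800)) for (p_b in c(0.03, 0.1)) {
    p <- exchange_params(kex, p_b, dw_H = 0.12, r2_0 = 5)
    mod <- sq_model_r2eff(p, s)
    orc <- vapply(s$nu_cpmg, oracle_sq_r2eff, numeric(1),
                  T_relax = 0.02, kex = kex, p_b = p_b,
                  dw_rad = ppm_to_rad(0.12, 800, "H")) + 5
    expect_lt(max(abs(mod - orc)), 0.05)
  }

  # fast exchange (kex >= 10 dw in rad/s): Luz-Meiboom within 1%
  p <- exchange_params(5000, 0.1, dw_H = 0.05, r2_0 = 10)
  sf <- cpmg_settings(0.02, c(50, 100, 250, 500, 1000), 600, "SQ_1H")
  lm_ <- luz_meiboom_r2eff(sf$nu_cpmg, 5000, 0.1,
                           ppm_to_rad(0.05, 600, "H"), 10)
  expect_lt(max(abs(sq_model_r2eff(p, sf) - lm_) / lm_), 0.01)

  # Carver-Richards closed form agrees with the propagator away from the
  # slow-exchange extreme
  for (kex in c(3000, 5000)) for (p_b in c(0.03, 0.1)) {
    p <- exchange_params(kex, p_b, dw_H = 0.05, r2_0 = 10)
    expect_lt(max(abs(sq_model_r2eff(p, sf, method = "cr72") -
                      sq_model_r2eff(p, sf))), 0.05)
  }
})

test_that("model curves obey the expected symmetries and limits", {
  s <- cpmg_settings(0.02, c(50, 100, 250, 1000), 800, "MQ_13C")
  # zero shift difference: flat at R2,0
  p0 <- exchange_params(400, 0.05, dw_C = 0, dw_H = 0, r2_0 = 7)
  expect_equal(mq_model_r2eff(p0, s), rep(7, 4), tolerance = 1e-10)
  expect_equal(sq_model_r2eff(p0, s), rep(7, 4), tolerance = 1e-10)

  # very fast exchange collapses the dispersion to R2,0 (the residual
  # plateau p_a p_b dw^2 / kex shrinks as 1/kex)
  pf <- exchange_params(1e7, 0.05, dw_C = 1.5, dw_H = 0.04, r2_0 = 7)
  expect_lt(max(abs(mq_model_r2eff(pf, s) - 7)), 0.1)

  # simultaneous sign flip of (dw_C, dw_H) leaves the curve unchanged
  pp <- exchange_params(400, 0.05, dw_C = 1.5, dw_H = 0.04, r2_0 = 7)
  pm <- exchange_params(400, 0.05, dw_C = -1.5, dw_H = -0.04, r2_0 = 7)
  expect_equal(mq_model_r2eff(pp, s), mq_model_r2eff(pm, s),
               tolerance = 1e-10)

  # doubling the field doubles dw in rad/s: same curve as doubling ppm
  s400 <- cpmg_settings(0.02, c(50, 100, 250, 1000), 400, "MQ_13C")
  p2 <- exchange_params(400, 0.05, dw_C = 3.0, dw_H = 0.08, r2_0 = 7)
  expect_equal(mq_model_r2eff(pp, s), mq_model_r2eff(p2, s400),
               tolerance = 1e-10)

  # in fast-intermediate exchange the returned quantity is a rate:
  # lengthening T_relax at the same nu grid does not change it
  sA <- cpmg_settings(0.02, c(50, 100, 250, 1000), 800, "SQ_1H")
  sB <- cpmg_settings(0.04, c(50, 100, 250, 1000), 800, "SQ_1H")
  pr <- exchange_params(2000, 0.05, dw_H = 0.05, r2_0 = 7)
  expect_lt(max(abs(sq_model_r2eff(pr, sA) - sq_model_r2eff(pr, sB))), 0.05)
})

test_that("noiseless global fits recover the generating parameters", {
  g <- list(T_relax = 0.02,
            nu_cpmg = c(50, 100, 100, 200, 300, 500, 750, 1000))
  for (kex in c(200, 800)) for (p_b in c(0.03, 0.1)) {
    truth <- exchange_params(kex, p_b, dw_C = 1.0, dw_H = 0.04, r2_0 = 15)
    st <- lapply(c(800, 600), function(f)
      cpmg_settings(g$T_relax, g$nu_cpmg, f, "MQ_13C"))
    sets <- gen_dispersion_dataset(truth, st, noise_fraction = 0,
                                   seed = 1, probe_id = "P")
    curves <- lapply(sets, function(d)
      r2eff_from_intensities(d$I, d$I0, d$settings, d$probe_id))
    fit <- fit_dispersion_global(curves)
    expect_lt(abs(fit$kex - kex) / kex, 0.005)
    expect_lt(abs(fit$p_b - p_b) / p_b, 0.005)
    expect_lt(abs(fit$probes$P[["dw_C"]] - 1.0), 0.005)
  }
})

test_that("flat curves are flagged as showing no detectable exchange", {
  s <- cpmg_settings(0.02, c(50, 100, 100, 200, 400, 600, 1000), 800,
                     "MQ_13C")
  cv <- r2eff_from_intensities(rep(1000 * exp(-0.02 * 12), 7), 1000, s,
                               probe_id = "flat")
  fit <- fit_dispersion_global(list(cv))
  expect_true(fit$no_exchange)
  expect_match(paste(fit$warnings, collapse = " "), "no detectable exchange")
})

test_that("under-determined groupings are rejected", {
  s <- cpmg_settings(0.02, c(50, 1000), 800, "MQ_13C")
  cv <- r2eff_from_intensities(c(900, 950), 1000, s, probe_id = "A")
  expect_error(fit_dispersion_global(list(cv)), "under-determined")
})
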