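# R1 / R1rho exponential fitting with Monte Carlo errors, R1rho -> R2
# offset correction, heteronuclear NOE, and helical-baseline deviation
# flags.

#' Fit a single-exponential decay to a relaxation series
#'
#' Fits I(t) = I0 * exp(-R * t) by weighted nonlinear least squares
#' (Levenberg-Marquardt, weights 1/sigma^2) with deterministic analytic
#' start values: I0 from the maximum intensity and R from a log-linear
#' regression of the positive intensities.  No multi-exponential model is
#' attempted.
#'
#' @param series a [relax_series()].
#' @return a `rate_result` list: `residue_id`, `experiment`, `rate`,
#'   `rate_error` (NA until [monte_carlo_error()] is run), `amplitude`,
#'   `amplitude_error`, `residuals`, `converged`, `n_mc`.
#' @export
fit_exponential <- function(series) {
  stopifnot(inherits(series, "relax_series"))
  if (!series$fittable)
    stop("series for residue ", series$residue_id,
         " has fewer than 2 distinct delays; not fittable")
  t <- series$delays; y <- series$intensities; s <- series$intensity_errors
  stopifnot(all(s > 0))
  start <- exp_start_values(t, y)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      fn = function(p) (y - p[["I0"]] * exp(-p[["R"]] * t)) / s,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 5, 9)) {
    return(structure(list(residue_id = series$residue_id,
                          experiment = series$experiment,
                          rate = NA_real_, rate_error = NA_real_,
                          amplitude = NA_real_, amplitude_error = NA_real_,
                          residuals = NULL, converged = FALSE,
                          diagnostics = if (is.null(fit)) "optimizer error"
                                        else fit$message,
                          n_mc = 0L),
                     class = "rate_result"))
  }
  p <- coef(fit)
  structure(list(residue_id = series$residue_id,
                 experiment = series$experiment,
                 rate = unname(p[["R"]]), rate_error = NA_real_,
                 amplitude = unname(p[["I0"]]), amplitude_error = NA_real_,
                 residuals = y - p[["I0"]] * exp(-p[["R"]] * t),
                 converged = TRUE, diagnostics = NULL, n_mc = 0L),
            class = "rate_result")
}

# I0 from the largest intensity; R from log-linear regression over the
# positive intensities (slope clamped at 0 so flat series start at R = 0).
exp_start_values <- function(t, y) {
  pos <- y > 0
  R0 <- if (sum(pos) >= 2 && length(unique(t[pos])) >= 2) {
    max(0, -unname(coef(lm(log(y[pos]) ~ t[pos]))[2]))
  } else 1
  c(I0 = max(y), R = R0)
}

#' Monte Carlo uncertainty for an exponential fit
#'
#' For each replicate, every intensity is resampled from a Gaussian
#' centred on the *measured* value with SD equal to its stated error, the
#' exponential is refit, and the SD of the replicate estimates is reported
#' as the parameter uncertainty.
#'
#' @param series the fitted [relax_series()].
#' @param fit result of [fit_exponential()] on `series`.
#' @param n_mc number of replicates (default 500).
#' @param seed integer seed; the same seed reproduces the same errors.
#' @param max_fail_fraction maximum tolerated fraction of non-converged
#'   replicates (default 0.1) before the call errors out.
#' @return `fit` with `rate_error`, `amplitude_error` and `n_mc` filled in.
#' @export
monte_carlo_error <- function(series, fit, n_mc = 500, seed = 1,
                              max_fail_fraction = 0.1) {
  stopifnot(inherits(series, "relax_series"), inherits(fit, "rate_result"),
            n_mc >= 2, fit$converged)
  t <- series$delays; y <- series$intensities; s <- series$intensity_errors
  draws <- with_substream(seed, paste0("mc_", series$residue_id, "_", series$experiment), {
    matrix(rnorm(n_mc * length(y), mean = rep(y, each = n_mc),
                 sd = rep(s, each = n_mc)), nrow = n_mc)
  })
  est <- matrix(NA_real_, n_mc, 2)
  for (i in seq_len(n_mc)) {
    yi <- draws[i, ]
    f <- tryCatch(
      minpack.lm::nls.lm(
        par = exp_start_values(t, yi),
        fn = function(p) (yi - p[["I0"]] * exp(-p[["R"]] * t)) / s,
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (!is.null(f) && !(f$info %in% c(0, 5, 9)))
      est[i, ] <- coef(f)[c("I0", "R")]
  }
  fail <- mean(is.na(est[, 2]))
  if (fail > max_fail_fraction)
    stop(sprintf("%.0f%% of Monte Carlo replicates failed to converge (residue %s)",
                 100 * fail, series$residue_id))
  fit$amplitude_error <- sd(est[, 1], na.rm = TRUE)
  fit$rate_error <- sd(est[, 2], na.rm = TRUE)
  fit$n_mc <- as.integer(n_mc)
  fit
}

#' Spin-lock settings for rotating-frame relaxation
#'
#' @param omega_sl spin-lock field strength omega in Hz.
#' @param offset offset Omega of the resonance from the carrier, in Hz.
#' @return `spinlock_settings` with the tilt angle
#'   theta = atan(omega / Omega) in degrees (90 on resonance).
#' @export
spinlock_settings <- function(omega_sl, offset = 0) {
  stopifnot(omega_sl > 0)
  theta <- if (offset == 0) 90 else atan(omega_sl / offset) * 180 / pi
  if (theta < 0) theta <- theta + 180  # keep in (0, 90] by |Omega| symmetry
  if (theta > 90) theta <- 180 - theta
  structure(list(omega_sl = omega_sl, offset = offset, theta = theta),
            class = "spinlock_settings")
}

#' Convert R1rho to R2 with offset correction
#'
#' R2 = R1rho / sin^2(theta) - R1 / tan^2(theta), where
#' theta = atan(omega / Omega) is the effective-field tilt angle.  The
#' uncertainty is propagated to first order treating R1rho and R1 as
#' independent.  On resonance (Omega = 0, theta = 90 deg) this reduces to
#' R2 = R1rho.
#'
#' @param r1rho,r1 `rate_result`s for the same residue (with errors).
#' @param sl a [spinlock_settings()].
#' @return list with `residue_id`, `r2`, `r2_error`, `theta`.
#' @export
r1rho_to_r2 <- function(r1rho, r1, sl) {
  stopifnot(inherits(sl, "spinlock_settings"),
            r1rho$residue_id == r1$residue_id)
  th <- sl$theta * pi / 180
  s2 <- sin(th)^2
  # 1/tan^2 written via cos^2/sin^2 so theta = 90 gives exactly 0
  ct2 <- cos(th)^2 / s2
  r2 <- r1rho$rate / s2 - r1$rate * ct2
  err <- sqrt((r1rho$rate_error / s2)^2 + (r1$rate_error * ct2)^2)
  list(residue_id = r1$residue_id, r2 = r2, r2_error = err, theta = sl$theta)
}

#' Heteronuclear NOE from a saturated/reference peak pair
#'
#' NOE = I_sat / I_ref, with the error from standard propagation:
#' sigma = |NOE| * sqrt((sigma_sat/I_sat)^2 + (sigma_ref/I_ref)^2).
#'
#' @param sat,ref single-row peak records (from a `peak_table`) for the
#'   same residue, from the experiments with and without 1H saturation.
#' @return `noe_result` list: `residue_id`, `noe`, `noe_error`.
#' @export
compute_noe <- function(sat, ref) {
  stopifnot(sat$residue_id == ref$residue_id)
  if (ref$height == 0) stop("reference intensity is zero for residue ",
                            ref$residue_id)
  noe <- sat$height / ref$height
  err <- if (sat$height == 0) {
    sat$height_error / abs(ref$height)
  } else {
    abs(noe) * sqrt((sat$height_error / sat$height)^2 +
                    (ref$height_error / ref$height)^2)
  }
  structure(list(residue_id = sat$residue_id, noe = noe, noe_error = err),
            class = "noe_result")
}

#' Flag residues deviating from the helical baseline
#'
#' For a well-ordered protein, R1 and NOE are uniform across residues in
#' stable helices; the helical mean +/- SD defines a baseline per
#' parameter.  A residue is flagged as having enhanced ps-ns dynamics when
#' its R1 exceeds baseline + k*SD *and* its NOE falls below
#' baseline - k*SD.
#'
#' @param results data.frame with columns `residue_id`, `r1`, `noe`.
#' @param helix_ranges list of `c(first, last)` residue ranges annotated
#'   as helical.
#' @param k number of SDs defining a deviation (default 2).
#' @return `results` with added columns `r1_baseline`, `r1_sd`,
#'   `noe_baseline`, `noe_sd`, `flag_dynamic`.
#' @export
baseline_and_flags <- function(results, helix_ranges, k = 2) {
  if (length(helix_ranges) == 0) stop("no helical annotation supplied")
  helical <- unique(unlist(lapply(helix_ranges, function(r) r[1]:r[2])))
  in_helix <- results$residue_id %in% helical &
    is.finite(results$r1) & is.finite(results$noe)
  if (sum(in_helix) < 5)
    stop("need at least 5 helical residues with data to set a baseline")
  r1_mu <- mean(results$r1[in_helix]);  r1_sd <- sd(results$r1[in_helix])
  noe_mu <- mean(results$noe[in_helix]); noe_sd <- sd(results$noe[in_helix])
  results$r1_baseline <- r1_mu;  results$r1_sd <- r1_sd
  results$noe_baseline <- noe_mu; results$noe_sd <- noe_sd
  results$flag_dynamic <- results$r1 > r1_mu + k * r1_sd &
    results$noe < noe_mu - k * noe_sd
  results
}
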