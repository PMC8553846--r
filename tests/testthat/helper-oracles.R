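# Independent oracles used across tests.  These deliberately share no code
# with the package: the CPMG oracle integrates the two-state ODE with a
# fine-step RK4 scheme instead of matrix exponentials, and the lineshape
# oracle measures volumes by direct grid summation.

# RK4 step for dm/dt = L m on a complex 2-vector.
ode_rk4 <- function(m, L, h) {
  k1 <- L %*% m
  k2 <- L %*% (m + h / 2 * k1)
  k3 <- L %*% (m + h / 2 * k2)
  k4 <- L %*% (m + h * k3)
  m + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

liouville <- function(kab, kba, x)
  matrix(c(-kab, kab, kba, -kba - 1i * x), 2, 2)

integrate_piece <- function(m, L, tau, h) {
  nstep <- max(1L, round(tau / h))
  for (q in seq_len(nstep)) m <- ode_rk4(m, L, tau / nstep)
  m
}

# Fine-step two-state MQ CPMG: 13C 180 pulses flip the sign of the carbon
# offset; both coherence-transfer pathways averaged; state-A detection.
oracle_mq_r2eff <- function(nu, T_relax, kex, p_b, dwH_rad, dwC_rad,
                            h = 2e-6) {
  kab <- p_b * kex; kba <- (1 - p_b) * kex; pa <- 1 - p_b
  n <- round(2 * nu * T_relax)
  tau <- T_relax / (2 * n)
  one_path <- function(s) {
    m <- c(pa + 0i, p_b + 0i)
    for (k in seq_len(n)) {
      m <- integrate_piece(m, liouville(kab, kba, dwH_rad + s * dwC_rad),
                           tau, h)
      s <- -s
      m <- integrate_piece(m, liouville(kab, kba, dwH_rad + s * dwC_rad),
                           tau, h)
    }
    Mod(m[1]) / pa
  }
  -log(0.5 * (one_path(1) + one_path(-1))) / T_relax
}

# Fine-step two-state SQ CPMG: 180 pulses conjugate the magnetization.
oracle_sq_r2eff <- function(nu, T_relax, kex, p_b, dw_rad, h = 2e-6) {
  kab <- p_b * kex; kba <- (1 - p_b) * kex; pa <- 1 - p_b
  n <- round(2 * nu * T_relax)
  tau <- T_relax / (2 * n)
  L <- liouville(kab, kba, dw_rad)
  m <- c(pa + 0i, p_b + 0i)
  for (k in seq_len(n)) {
    m <- integrate_piece(m, L, tau, h)
    m <- Conj(m)
    m <- integrate_piece(m, L, tau, h)
  }
  -log(Mod(m[1]) / pa) / T_relax
}

ppm_to_rad <- function(ppm, field_1H, nucleus = c("H", "C")) {
  nucleus <- match.arg(nucleus)
  ratio <- c(H = 1, C = 0.251504)[[nucleus]]
  2 * pi * ppm * field_1H * ratio
}

# Direct-summation volume of a grid region nearest to a given position
# (split at midpoints between peak positions along x).
grid_volume_split <- function(grid, positions_x) {
  o <- order(positions_x)
  s <- positions_x[o]
  cuts <- c(-Inf, (head(s, -1) + tail(s, -1)) / 2, Inf)
  dx <- mean(diff(grid$x)); dy <- mean(diff(grid$y))
  vols <- vapply(seq_along(s), function(i) {
    band <- grid$x > cuts[i] & grid$x <= cuts[i + 1]
    sum(grid$z[band, ]) * dx * dy
  }, numeric(1))
  vols[order(o)]
}

# Convenience: dispersion curves from a preset at a given seed.
preset_curves <- function(preset_name, seed, noise_fraction = NULL) {
  pr <- spinflex_preset(preset_name)
  sets <- gen_preset_dispersion(pr, seed = seed,
                                noise_fraction = noise_fraction)
  lapply(sets, function(d)
    r2eff_from_intensities(d$I, d$I0, d$settings, d$probe_id))
}
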