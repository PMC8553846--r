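# Synthetic-data generators: every input the pipeline consumes can be
# produced here with known ground truth, so each analysis stage is
# testable end to end without spectrometer data.
#
# Random-stream policy: every generator derives an independent substream
# from (seed, label), so adding a generator or reordering calls never
# perturbs existing fixtures.

#' Shipped CPMG frequency grids
#'
#' Constant-time CPMG grids as used in the emulated experiments:
#' `"K_MQ"` (T_relax = 20 ms, 50-1000 Hz, duplicates at 200 and 600 Hz),
#' `"Na_MQ"` (T_relax = 30 ms, 33.33-1000 Hz, duplicates at 133.33,
#' 266.67 and 533.33 Hz) and `"Na_SQ"` (T_relax = 20 ms, 50-1000 Hz,
#' duplicates at 100, 400 and 600 Hz).  Every grid satisfies the
#' even-pulse-count constraint at its T_relax.
#'
#' @param name grid name.
#' @return list with `T_relax` (s) and `nu_cpmg` (s^-1, replicates
#'   repeated).
#' @export
cpmg_grid <- function(name = c("K_MQ", "Na_MQ", "Na_SQ")) {
  name <- match.arg(name)
  switch(name,
    K_MQ = list(T_relax = 0.020,
                nu_cpmg = c(50, 100, 200, 200, 250, 300, 350, 400, 500,
                            600, 600, 800, 1000)),
    Na_MQ = list(T_relax = 0.030,
                 nu_cpmg = c(33.33, 66.67, 100, 133.33, 133.33, 166.67,
                             200, 233.33, 266.67, 266.67, 300, 333.33,
                             366.67, 400, 466.67, 533.33, 533.33, 600,
                             666.67, 800, 900, 1000)),
    Na_SQ = list(T_relax = 0.020,
                 nu_cpmg = c(50, 100, 100, 150, 200, 250, 300, 350, 400,
                             400, 450, 500, 600, 600, 700, 800, 900, 1000)))
}

#' Named synthetic presets
#'
#' Versioned, immutable parameter sets used by the generators and the
#' recovery tests.  Parameters not fixed by the emulated measurements
#' (minor-state population, shift differences, exchange-free rates,
#' linewidths) are listed under `$assumed` and must never be used as
#' reference values; the remaining entries are the quantities the
#' analyses are expected to recover.
#'
#' * `"N68_K"` — heteronuclear NOE pair, true NOE 0.43.
#' * `"nak_na_sf"` — two methyl probes (V64-like, V59-like), 13C MQ
#'   dispersion at 800 and 600 MHz on the Na+ grid, kex = 390 s^-1.
#' * `"nak_na_sf_sq"` — one MQ probe (V59-like) plus one 1H SQ probe
#'   (L48-like), kex = 356 s^-1.
#' * `"L48a_K"` — three-state methyl cluster, populations 0.86/0.07/0.07.
#' * `"L48a_Na"` — three-state methyl cluster, populations 0.47/0.37/0.16.
#'
#' @param name preset name.
#' @return preset list (contents depend on the preset kind).
#' @export
spinflex_preset <- function(name = c("N68_K", "nak_na_sf", "nak_na_sf_sq",
                                     "L48a_K", "L48a_Na")) {
  name <- match.arg(name)
  version <- "1"
  switch(name,
    N68_K = list(name = name, version = version, kind = "noe",
                 noe_true = 0.43, I_ref = 1e5, noise_fraction = 0.02),
    nak_na_sf = list(
      name = name, version = version, kind = "dispersion",
      kex = 390, fields = c(800, 600), grid = "Na_MQ",
      noise_fraction = 0.02,
      probes = list(
        V64 = list(coherence = "MQ_13C", dw_C = 1.5, dw_H = 0.04),
        V59 = list(coherence = "MQ_13C", dw_C = 0.25, dw_H = 0.02)),
      assumed = list(
        p_b = 0.05, r2_0 = 20, dw = "all dw values",
        note = paste("p_b, dw and R2,0 are plausible assumptions, not",
                     "measured values; dw_C per probe calibrated so the",
                     "endpoint Rex at 800 MHz reproduces the reported",
                     "~15 Hz (V64-like) and ~4 Hz (V59-like) magnitudes;",
                     "methyl dw_H kept small because the 1H part of the",
                     "MQ phase is not refocused by the 13C pulse train")),
      p_b = 0.05, r2_0 = 20),
    nak_na_sf_sq = list(
      name = name, version = version, kind = "dispersion",
      kex = 356, fields = c(800, 600), sq_fields = c(900, 600),
      grid = "Na_MQ", sq_grid = "Na_SQ", noise_fraction = 0.02,
      probes = list(
        V59 = list(coherence = "MQ_13C", dw_C = 0.25, dw_H = 0.02),
        L48 = list(coherence = "SQ_1H", dw_C = 0, dw_H = 0.10)),
      assumed = list(
        p_b = 0.05, r2_0 = 20, dw = "all dw values",
        note = paste("p_b, dw and R2,0 are plausible assumptions, not",
                     "measured values; dw chosen as for nak_na_sf, with",
                     "an L48-like 1H SQ probe showing a clear dispersion")),
      p_b = 0.05, r2_0 = 20),
    L48a_K = cluster_preset(name, version, c(0.86, 0.07, 0.07)),
    L48a_Na = cluster_preset(name, version, c(0.47, 0.37, 0.16)))
}

# Three partially overlapped methyl resonances: major state near 0.3 ppm
# (1H), minor states near 0.4 and 0.2 ppm, leucine-delta-like 13C shifts.
cluster_preset <- function(name, version, populations) {
  list(name = name, version = version, kind = "cluster",
       positions = rbind(c(0.30, 24.0), c(0.40, 24.25), c(0.20, 23.8)),
       linewidths = rbind(c(0.020, 0.18), c(0.020, 0.18), c(0.020, 0.18)),
       populations = populations,
       grid = list(x = seq(0.05, 0.55, length.out = 121),
                   y = seq(23.0, 25.0, length.out = 101)),
       noise_fraction = 0.01,
       assumed = list(positions = "approximate", linewidths = "assumed"))
}

#' Generate a noisy single-exponential relaxation decay
#'
#' intensities = I0 * exp(-R t) + Normal(0, noise_fraction * I0), with
#' per-point errors max(noise_fraction * I0, 0.02 * |intensity|).
#'
#' @param R decay rate in s^-1 (>= 0).
#' @param I0 initial intensity.
#' @param delays delays in seconds.
#' @param noise_fraction Gaussian noise SD as a fraction of I0.
#' @param seed integer seed.
#' @param residue_id,experiment series metadata.
#' @return a [relax_series()].
#' @export
gen_decay_series <- function(R, I0 = 1e5,
                             delays = c(0, 0.4, 1.4, 2.4, 3.6),
                             noise_fraction = 0.02, seed = 1,
                             residue_id = 1L, experiment = "R1") {
  stopifnot(R >= 0, length(delays) > 0, noise_fraction >= 0)
  y0 <- I0 * exp(-R * delays)
  eps <- with_substream(seed, paste0("decay_", residue_id, "_", experiment),
                        rnorm(length(delays), 0, 1))
  y <- y0 + noise_fraction * I0 * eps
  err <- pmax(noise_fraction * I0, 0.02 * abs(y))
  relax_series(residue_id, experiment, delays, y, err)
}

#' Generate a saturated/reference NOE peak pair
#'
#' The reference intensity is centred on `I_ref` and the saturated
#' intensity on `noe_true * I_ref`; both carry Gaussian noise of SD
#' `noise_fraction * I_ref` (base-plane noise is absolute, so both peaks
#' share it).  Stated errors are the noise SD, floored at 2\% of the
#' height.
#'
#' @param noe_true true NOE ratio.
#' @param I_ref reference intensity.
#' @param noise_fraction noise SD as a fraction of `I_ref`.
#' @param seed integer seed.
#' @param residue_id residue number.
#' @return list with elements `sat` and `ref`, each a one-row peak
#'   data.frame usable by [compute_noe()].
#' @export
gen_noe_pair <- function(noe_true, I_ref = 1e5, noise_fraction = 0.02,
                         seed = 1, residue_id = 68L) {
  stopifnot(noise_fraction >= 0)
  eps <- with_substream(seed, paste0("noe_", residue_id),
                        rnorm(2, 0, 1))
  h_sat <- noe_true * I_ref + noise_fraction * I_ref * eps[1]
  h_ref <- I_ref + noise_fraction * I_ref * eps[2]
  mk <- function(h) data.frame(
    residue_id = residue_id, atom_label = "N",
    shift_w1 = 8.5, shift_w2 = 118.0, height = h,
    height_error = max(noise_fraction * I_ref, 0.02 * abs(h)))
  list(sat = mk(h_sat), ref = mk(h_ref))
}

#' Generate CPMG intensity datasets from two-state exchange parameters
#'
#' For each settings entry, the model R2,eff is evaluated on the full
#' (replicates included) nu grid with the coherence-appropriate model and
#' intensities are drawn as
#' I(nu) = I0 * exp(-R2,eff(nu) * T_relax) * (1 + Normal(0, noise));
#' replicate nu points receive independent noise.
#'
#' @param params an [exchange_params()].
#' @param settings_list list of [cpmg_settings()].
#' @param noise_fraction fractional intensity noise.
#' @param seed integer seed.
#' @param probe_id probe identifier.
#' @param I0 reference intensity.
#' @param stream_label label the random substream is derived from
#'   (defaults to `probe_id`; preset expansion prefixes the preset name so
#'   the same probe gets independent noise in different presets).
#' @return list of datasets, one per settings entry, each with `probe_id`,
#'   `settings`, `I`, `I0`, `truth` (the generating parameters).
#' @export
gen_dispersion_dataset <- function(params, settings_list,
                                   noise_fraction = 0.02, seed = 1,
                                   probe_id = "probe", I0 = 1e6,
                                   stream_label = probe_id) {
  stopifnot(inherits(params, "exchange_params"), noise_fraction >= 0)
  lapply(seq_along(settings_list), function(k) {
    s <- settings_list[[k]]
    r2 <- if (s$coherence == "MQ_13C") mq_model_r2eff(params, s)
          else sq_model_r2eff(params, s)
    eps <- with_substream(seed, paste0("cpmg_", stream_label, "_", k,
                                       "_", s$field_1H, s$coherence),
                          rnorm(length(r2), 0, 1))
    I <- I0 * exp(-r2 * s$T_relax) * (1 + noise_fraction * eps)
    list(probe_id = probe_id, settings = s, I = I, I0 = I0, truth = params)
  })
}

#' Generate a cluster of overlapping 2D Lorentzian peaks
#'
#' Component volumes are proportional to the requested fractional
#' populations; Gaussian noise (SD = `noise_fraction` times the maximum
#' noiseless intensity) is added to every grid point.
#'
#' @param positions n x 2 matrix of peak positions (ppm: direct, indirect).
#' @param linewidths n x 2 matrix of half-widths at half-maximum (ppm).
#' @param populations fractional populations, summing to 1.
#' @param grid list with numeric vectors `x` and `y` (ppm axes).
#' @param noise_fraction grid noise as a fraction of the maximum.
#' @param seed integer seed.
#' @param total_volume overall scale of the summed peak volumes.
#' @return list `x`, `y`, `z` (matrix), plus `truth` (generating
#'   parameters).
#' @export
gen_peak_cluster <- function(positions, linewidths, populations, grid,
                             noise_fraction = 0.01, seed = 1,
                             total_volume = 1e4) {
  positions <- as.matrix(positions); linewidths <- as.matrix(linewidths)
  stopifnot(abs(sum(populations) - 1) < 1e-6,
            all(populations >= 0), all(populations <= 1),
            nrow(positions) == length(populations),
            nrow(linewidths) == length(populations))
  z <- 0
  for (i in seq_along(populations)) {
    vol <- total_volume * populations[i]
    A <- vol / (pi^2 * linewidths[i, 1] * linewidths[i, 2])
    z <- z + lorentz2d(grid$x, grid$y, positions[i, 1], positions[i, 2],
                       linewidths[i, 1], linewidths[i, 2], A)
  }
  if (noise_fraction > 0) {
    eps <- with_substream(seed, "cluster",
                          rnorm(length(z), 0, noise_fraction * max(z)))
    z <- z + matrix(eps, nrow(z), ncol(z))
  }
  list(x = grid$x, y = grid$y, z = z,
       truth = list(positions = positions, linewidths = linewidths,
                    populations = populations))
}

#' Generate paired-condition chemical shift tables
#'
#' Condition-1 shifts are drawn once from typical amide ranges;
#' condition-2 shifts equal condition-1 plus the specified effect for the
#' perturbed residues plus Gaussian measurement noise (applied to all
#' residues in both dimensions).
#'
#' @param n_residues number of residues (numbered 1..n).
#' @param perturbed data.frame with columns `residue`, `d_H`, `d_X`
#'   (effect sizes in ppm); may be empty.
#' @param noise_ppm SD of the shift noise in ppm (applied to both
#'   dimensions of condition 2).
#' @param seed integer seed.
#' @return list with `cond1`, `cond2` (shift tables: `residue`, `atom`,
#'   `shift_H`, `shift_X`) and `truth` (the perturbed set).
#' @export
gen_csp_tables <- function(n_residues, perturbed = NULL, noise_ppm = 0,
                           seed = 1) {
  stopifnot(n_residues >= 1, noise_ppm >= 0)
  if (is.null(perturbed))
    perturbed <- data.frame(residue = integer(), d_H = numeric(),
                            d_X = numeric())
  draws <- with_substream(seed, "csp_tables", {
    list(H = rnorm(n_residues, 8.3, 0.4), X = rnorm(n_residues, 119, 3.5),
         eH = rnorm(n_residues, 0, 1), eX = rnorm(n_residues, 0, 1))
  })
  cond1 <- data.frame(residue = seq_len(n_residues), atom = "N",
                      shift_H = draws$H, shift_X = draws$X)
  dH <- dX <- numeric(n_residues)
  idx <- match(perturbed$residue, cond1$residue)
  dH[idx] <- perturbed$d_H; dX[idx] <- perturbed$d_X
  cond2 <- cond1
  cond2$shift_H <- cond1$shift_H + dH + noise_ppm * draws$eH
  cond2$shift_X <- cond1$shift_X + dX + noise_ppm * draws$eX
  list(cond1 = cond1, cond2 = cond2, truth = perturbed)
}

#' Build the settings and datasets for a dispersion preset
#'
#' Expands a `"nak_na_sf"`-style preset into per-probe, per-field
#' [cpmg_settings()] and simulated intensity datasets.
#'
#' @param preset result of [spinflex_preset()] with `kind = "dispersion"`.
#' @param seed integer seed.
#' @param noise_fraction overrides the preset noise when non-`NULL`.
#' @return list of datasets as produced by [gen_dispersion_dataset()],
#'   concatenated over probes and fields.
#' @export
gen_preset_dispersion <- function(preset, seed = 1, noise_fraction = NULL) {
  stopifnot(identical(preset$kind, "dispersion"))
  nf <- if (is.null(noise_fraction)) preset$noise_fraction else noise_fraction
  out <- list()
  for (pname in names(preset$probes)) {
    pr <- preset$probes[[pname]]
    if (pr$coherence == "MQ_13C") {
      g <- cpmg_grid(preset$grid); fields <- preset$fields
    } else {
      g <- cpmg_grid(preset$sq_grid); fields <- preset$sq_fields
    }
    st <- lapply(fields, function(f)
      cpmg_settings(g$T_relax, g$nu_cpmg, f, pr$coherence))
    pars <- exchange_params(preset$kex, preset$p_b, pr$dw_C, pr$dw_H,
                            preset$r2_0)
    out <- c(out, gen_dispersion_dataset(
      pars, st, nf, seed = seed, probe_id = pname,
      stream_label = paste(preset$name, pname)))
  }
  out
}
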