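# End-to-end pipeline driver: simulate inputs from presets, run the
# analysis stages in dependency order, and emit per-residue result tables,
# structure-attribute files and a run summary with file digests.

#' Run the analysis pipeline from a configuration
#'
#' Executes the stages requested in `config$stages` in dependency order:
#' `simulate` (write synthetic inputs from presets), `fit_relax` (R1 and
#' R1rho exponential fits with Monte Carlo errors, R2 via offset
#' correction), `noe`, `csp`, `populations`, `cpmg` (R2,eff, Rex and
#' optionally the global exchange fit), and `report`.  Per-residue
#' failures are isolated and recorded as warnings in the run summary,
#' never silently dropped.  All randomness derives from `config$seed`.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @param out_dir output directory (created if missing).
#' @return a `run_summary` list: `config`, `version`, `seed`, `files`
#'   (name -> md5 digest), `warnings`, `results` (in-memory stage
#'   outputs).  Also written as `run_summary.json` in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  if (is.null(stages)) stop("config has no 'stages' entry")
  warnings <- character()
  results <- list()
  note <- function(msg) warnings <<- c(warnings, msg)
  path <- function(f) file.path(out_dir, f)

  if (!is.null(stages$simulate))
    results$inputs <- stage_simulate(stages$simulate, config$seed, out_dir)

  if (!is.null(stages$fit_relax)) {
    st <- stages$fit_relax
    n_mc <- if (is.null(st$mc_replicates)) config$mc_replicates
            else st$mc_replicates
    rows <- list()
    for (exp_name in c("R1", "R1rho")) {
      f <- path(sprintf("inputs/%s_series.tsv", tolower(exp_name)))
      if (!file.exists(f)) next
      series <- read_series_table(f, experiment = exp_name,
                                  noise_fraction = config$error_floor)
      for (s in series) {
        if (!s$fittable) {
          note(sprintf("residue %d (%s): unfittable (<2 points)",
                       s$residue_id, exp_name))
          next
        }
        fit <- fit_exponential(s)
        if (!fit$converged) {
          note(sprintf("residue %d (%s): fit did not converge",
                       s$residue_id, exp_name))
          next
        }
        fit <- monte_carlo_error(s, fit, n_mc = n_mc, seed = config$seed)
        rows[[length(rows) + 1]] <- data.frame(
          residue = s$residue_id, experiment = exp_name,
          rate = fit$rate, rate_error = fit$rate_error,
          amplitude = fit$amplitude, n_mc = fit$n_mc)
      }
    }
    rates <- do.call(rbind, rows)
    write.csv(rates, path("rates.csv"), row.names = FALSE)
    results$rates <- rates
    r2 <- merge_r1rho(rates, st)
    if (!is.null(r2)) {
      write.csv(r2, path("r2.csv"), row.names = FALSE)
      results$r2 <- r2
    }
  }

  if (!is.null(stages$noe)) {
    sat <- read_peak_list(path("inputs/noe_sat.tsv"), "tsv",
                          error_floor = config$error_floor)
    ref <- read_peak_list(path("inputs/noe_ref.tsv"), "tsv",
                          error_floor = config$error_floor)
    rows <- list()
    for (i in seq_len(nrow(ref))) {
      j <- which(sat$residue_id == ref$residue_id[i] &
                 sat$atom_label == ref$atom_label[i])
      if (length(j) != 1) {
        note(sprintf("residue %d: no saturated counterpart",
                     ref$residue_id[i]))
        next
      }
      r <- compute_noe(sat[j, ], ref[i, ])
      rows[[length(rows) + 1]] <- data.frame(
        residue = r$residue_id, noe = r$noe, noe_error = r$noe_error)
    }
    noe <- do.call(rbind, rows)
    write.csv(noe, path("noe.csv"), row.names = FALSE)
    results$noe <- noe
  }

  if (!is.null(stages$csp)) {
    cond1 <- read_shift_table(path("inputs/shifts_cond1.tsv"))
    cond2 <- read_shift_table(path("inputs/shifts_cond2.tsv"))
    tab <- csp_table(cond1, cond2, nucleus = "N", weights = config$weights,
                     trim_fraction = config$trim_fraction,
                     sigma_factor = config$threshold_sigma_factor)
    thr <- attr(tab, "threshold")
    write.csv(tab, path("csp.csv"), row.names = FALSE)
    ok <- tab$comparable
    write_residue_attributes(setNames(tab$csp[ok], tab$residue_id[ok]),
                             path("csp.attr"), "csp")
    results$csp <- tab
    results$csp_threshold <- thr
  }

  if (!is.null(stages$populations)) {
    st <- stages$populations
    grid <- read_grid_csv(path("inputs/cluster.csv"))
    init <- matrix(unlist(st$init_positions), ncol = 2, byrow = TRUE)
    pops <- quantify_populations(grid, n_states = st$n_states,
                                 init_positions = init)
    jsonlite::write_json(
      list(populations = pops$populations,
           positions = pops$positions, mode = pops$mode),
      path("populations.json"), auto_unbox = TRUE, digits = NA)
    results$populations <- pops
  }

  if (!is.null(stages$cpmg)) {
    st <- stages$cpmg
    meta <- jsonlite::read_json(path("inputs/cpmg_meta.json"),
                                simplifyVector = TRUE)
    curves <- list(); rex_rows <- list()
    for (k in seq_len(nrow(meta))) {
      tab <- read.table(path(meta$file[k]), header = TRUE, sep = "\t")
      s <- cpmg_settings(meta$T_relax[k], tab$nu, meta$field_1H[k],
                         meta$coherence[k])
      cv <- r2eff_from_intensities(tab$I, meta$I0[k], s,
                                   probe_id = meta$probe[k])
      curves[[length(curves) + 1]] <- cv
      rx <- rex_estimate(cv)
      rex_rows[[length(rex_rows) + 1]] <- data.frame(
        probe = meta$probe[k], field_1H = meta$field_1H[k],
        coherence = meta$coherence[k], rex = rx$rex,
        rex_error = rx$rex_error, note = rx$note)
    }
    rex <- do.call(rbind, rex_rows)
    write.csv(rex, path("rex.csv"), row.names = FALSE)
    results$rex <- rex
    results$curves <- curves
    if (isTRUE(st$fit)) {
      fit <- fit_dispersion_global(curves)
      for (w in fit$warnings) note(paste0("cpmg fit: ", w))
      jsonlite::write_json(
        list(kex = fit$kex, kex_error = fit$kex_error, p_b = fit$p_b,
             reduced_chisq = fit$reduced_chisq,
             no_exchange = fit$no_exchange, warnings = fit$warnings),
        path("fit.json"), auto_unbox = TRUE, digits = NA)
      results$fit <- fit
    }
  }

  if (!is.null(stages$report))
    results$report <- generate_report(results, out_dir)

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("run_summary\\.json$", files)]
  digests <- tools::md5sum(files)
  names(digests) <- sub(paste0("^", out_dir, "/?"), "", names(digests))
  summary <- structure(list(
    config = unclass(config)[setdiff(names(config), "weights")],
    weights = unclass(config$weights),
    version = as.character(utils::packageVersion("spinflex")),
    seed = config$seed, files = as.list(digests),
    warnings = warnings, results = results), class = "run_summary")
  jsonlite::write_json(summary[setdiff(names(summary), "results")],
                       file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  summary
}

# Write synthetic inputs for the requested stages into out_dir/inputs.
stage_simulate <- function(sim, seed, out_dir) {
  ind <- file.path(out_dir, "inputs")
  dir.create(ind, showWarnings = FALSE, recursive = TRUE)
  made <- character()
  if (!is.null(sim$relax)) {
    prof <- sim$relax
    prof$r1 <- as.numeric(unlist(prof$r1))
    prof$r1rho <- as.numeric(unlist(prof$r1rho))
    resid <- seq_len(length(prof$r1))
    for (exp_name in c("R1", "R1rho")) {
      rates <- if (exp_name == "R1") prof$r1 else prof$r1rho
      delays <- if (exp_name == "R1") c(0, 0.4, 1.4, 2.4, 3.6)
                else c(0.002, 0.008, 0.012, 0.018, 0.025)
      series <- lapply(resid, function(i)
        gen_decay_series(rates[i], delays = delays,
                         noise_fraction = prof$noise %||% 0.02,
                         seed = seed, residue_id = i,
                         experiment = exp_name))
      f <- file.path(ind, sprintf("%s_series.tsv", tolower(exp_name)))
      write_series_table(series, f)
      made <- c(made, f)
    }
  }
  if (!is.null(sim$noe_preset)) {
    pr <- spinflex_preset(sim$noe_preset)
    pair <- gen_noe_pair(pr$noe_true, pr$I_ref, pr$noise_fraction, seed)
    write_noe_peaks <- function(pk, f) {
      df <- data.frame(residue = pk$residue_id, atom = pk$atom_label,
                       shift_w1 = pk$shift_w1, shift_w2 = pk$shift_w2,
                       height = pk$height, height_error = pk$height_error)
      write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_noe_peaks(pair$sat, file.path(ind, "noe_sat.tsv"))
    write_noe_peaks(pair$ref, file.path(ind, "noe_ref.tsv"))
  }
  if (!is.null(sim$csp)) {
    tabs <- gen_csp_tables(sim$csp$n_residues %||% 30,
                           as.data.frame(sim$csp$perturbed),
                           noise_ppm = sim$csp$noise_ppm %||% 0.002,
                           seed = seed)
    write.table(tabs$cond1, file.path(ind, "shifts_cond1.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(tabs$cond2, file.path(ind, "shifts_cond2.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(sim$cluster_preset)) {
    pr <- spinflex_preset(sim$cluster_preset)
    grid <- gen_peak_cluster(pr$positions, pr$linewidths, pr$populations,
                             pr$grid, pr$noise_fraction, seed)
    write_grid_csv(grid, file.path(ind, "cluster.csv"))
  }
  if (!is.null(sim$cpmg_preset)) {
    pr <- spinflex_preset(sim$cpmg_preset)
    sets <- gen_preset_dispersion(pr, seed = seed)
    meta <- list()
    for (k in seq_along(sets)) {
      d <- sets[[k]]
      f <- sprintf("inputs/cpmg_%s_%g_%s.tsv", d$probe_id,
                   d$settings$field_1H, d$settings$coherence)
      write.table(data.frame(nu = d$settings$nu_cpmg, I = d$I),
                  file.path(out_dir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      meta[[k]] <- data.frame(probe = d$probe_id, file = f,
                              T_relax = d$settings$T_relax,
                              field_1H = d$settings$field_1H,
                              coherence = d$settings$coherence, I0 = d$I0)
    }
    jsonlite::write_json(do.call(rbind, meta),
                         file.path(ind, "cpmg_meta.json"), digits = NA)
  }
  ind
}

`%||%` <- function(a, b) if (is.null(a)) b else a

merge_r1rho <- function(rates, st) {
  r1 <- rates[rates$experiment == "R1", ]
  rr <- rates[rates$experiment == "R1rho", ]
  if (!nrow(r1) || !nrow(rr)) return(NULL)
  sl <- spinlock_settings(st$omega_sl %||% 1923, st$offset %||% 0)
  common <- intersect(r1$residue, rr$residue)
  do.call(rbind, lapply(common, function(res) {
    a <- rr[rr$residue == res, ][1, ]; b <- r1[r1$residue == res, ][1, ]
    v <- r1rho_to_r2(list(residue_id = res, rate = a$rate,
                          rate_error = a$rate_error),
                     list(residue_id = res, rate = b$rate,
                          rate_error = b$rate_error), sl)
    data.frame(residue = res, r2 = v$r2, r2_error = v$r2_error,
               theta = v$theta)
  }))
}

#' Merge stage outputs into a per-residue report
#'
#' Builds one merged table with a row for every residue seen by any
#' stage and columns for R1, R2, NOE, CSP (with significance) and Rex;
#' numerical values are taken verbatim from the stage outputs (nothing is
#' recomputed here).  The CSP threshold is recorded numerically alongside.
#'
#' @param results in-memory stage outputs from [run_pipeline()].
#' @param out_dir directory to write `report.csv` into.
#' @return list: `table` (merged data.frame), `csp_threshold`.
#' @export
generate_report <- function(results, out_dir) {
  have <- intersect(c("rates", "r2", "noe", "csp", "rex"), names(results))
  if (!length(have)) stop("no stage outputs to report on")
  resid <- sort(unique(c(
    if (!is.null(results$rates)) results$rates$residue,
    if (!is.null(results$noe)) results$noe$residue,
    if (!is.null(results$csp)) results$csp$residue_id)))
  tab <- data.frame(residue = resid)
  if (!is.null(results$rates)) {
    r1 <- results$rates[results$rates$experiment == "R1", ]
    tab$r1 <- r1$rate[match(resid, r1$residue)]
    tab$r1_error <- r1$rate_error[match(resid, r1$residue)]
  }
  if (!is.null(results$r2)) {
    tab$r2 <- results$r2$r2[match(resid, results$r2$residue)]
    tab$r2_error <- results$r2$r2_error[match(resid, results$r2$residue)]
  }
  if (!is.null(results$noe)) {
    tab$noe <- results$noe$noe[match(resid, results$noe$residue)]
    tab$noe_error <- results$noe$noe_error[match(resid, results$noe$residue)]
  }
  thr <- NULL
  if (!is.null(results$csp)) {
    tab$csp <- results$csp$csp[match(resid, results$csp$residue_id)]
    tab$csp_significant <-
      results$csp$significant[match(resid, results$csp$residue_id)]
    thr <- results$csp_threshold$threshold
  }
  write.csv(tab, file.path(out_dir, "report.csv"), row.names = FALSE)
  list(table = tab, csp_threshold = thr)
}
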