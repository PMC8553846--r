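# Chemical shift perturbation mapping between two ionic conditions, the
# trimmed-mean significance rule, and multi-state peak population
# quantification by 2D Lorentzian deconvolution.

#' Weighted chemical shift perturbation for one residue
#'
#' CSP = sqrt(ddH^2 + (W * ddX)^2), where ddH and ddX are the 1H and
#' heteronucleus shift differences between the two conditions and W is the
#' gyromagnetic-ratio weight for the heteronucleus (W_N for amides, W_C
#' for methyls).  The CSP depends only on the magnitudes of the
#' differences, so it is invariant under swapping the conditions.
#'
#' @param shift_pair_H 1H shifts `c(cond1, cond2)` in ppm.
#' @param shift_pair_X heteronucleus shifts `c(cond1, cond2)` in ppm.
#' @param nucleus `"N"` or `"C"`.
#' @param weights a [csp_weights()].
#' @param residue_id,atom_label optional identifiers carried through.
#' @return `csp_record` list: `residue_id`, `atom_label`, `delta_H`,
#'   `delta_X` (signed, cond2 - cond1), `csp`, `significant` (NA until
#'   thresholded).
#' @export
compute_csp <- function(shift_pair_H, shift_pair_X, nucleus = c("N", "C"),
                        weights = csp_weights(), residue_id = NA_integer_,
                        atom_label = NA_character_) {
  nucleus <- match.arg(nucleus)
  stopifnot(all(is.finite(shift_pair_H)), all(is.finite(shift_pair_X)),
            inherits(weights, "csp_weights"))
  dH <- delta_shift(shift_pair_H)
  dX <- delta_shift(shift_pair_X)
  W <- if (nucleus == "N") weights$W_N else weights$W_C
  structure(list(residue_id = residue_id, atom_label = atom_label,
                 delta_H = dH, delta_X = dX,
                 csp = sqrt(dH^2 + (W * dX)^2), significant = NA),
            class = "csp_record")
}

#' Signed chemical shift difference
#'
#' Condition 2 minus condition 1, in ppm.  Carbonyl and Calpha differences
#' are reported unweighted through this function; thresholding downstream
#' uses the magnitude.
#'
#' @param shift_pair `c(cond1, cond2)` in ppm.
#' @return signed difference in ppm.
#' @export
delta_shift <- function(shift_pair) {
  stopifnot(length(shift_pair) == 2, all(is.finite(shift_pair)))
  shift_pair[2] - shift_pair[1]
}

#' Trimmed-mean significance threshold for CSP profiles
#'
#' threshold = trimmed mean + sigma_factor * SD(trimmed set).  The trimmed
#' mean discards `trim_fraction` of the values from *each* tail (so the
#' conventional "10\% trimmed mean" drops the bottom and top deciles), and
#' the SD is computed on the same trimmed set, making the rule robust to
#' the large perturbations it is meant to detect.
#'
#' @param values CSP or |delta-shift| values, one per residue, names used
#'   to report exceeding residues.
#' @param trim_fraction fraction trimmed from each tail (default 0.10).
#' @param sigma_factor SD multiplier (default 1.5).
#' @return list: `threshold` (ppm), `trimmed_mean`, `trimmed_sd`,
#'   `exceeding` (names of values above threshold), `rule` (text record of
#'   the convention used).
#' @export
significance_threshold <- function(values, trim_fraction = 0.10,
                                   sigma_factor = 1.5) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite values supplied")
  if (length(values) < 5)
    stop("need at least 5 values for a meaningful threshold")
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5)
  n_drop <- floor(length(values) * trim_fraction)
  s <- sort(values)
  trimmed <- s[seq.int(n_drop + 1, length(values) - n_drop)]
  mu <- mean(trimmed)
  sdv <- if (length(trimmed) > 1) sd(trimmed) else 0
  thr <- mu + sigma_factor * sdv
  list(threshold = thr, trimmed_mean = mu, trimmed_sd = sdv,
       exceeding = names(values)[values > thr],
       rule = sprintf(
         "trimmed mean (%g from each tail) + %g * SD of trimmed set",
         trim_fraction, sigma_factor))
}

#' Compare two shift tables and build a CSP table
#'
#' Rows are matched on (residue, atom).  Peaks present in only one
#' condition (e.g. exchange-broadened in the other) are reported with
#' `comparable = FALSE` and `csp = NA`, never as CSP = 0.  When a residue
#' has several resonances in one condition only (minor states), the major
#' state -- the row supplied in the main table -- is used for the CSP and
#' the extras should be listed separately by the caller.
#'
#' @param cond1,cond2 shift tables (see [read_shift_table()]).
#' @param nucleus `"N"` or `"C"` (selects the CSP weight).
#' @param weights a [csp_weights()].
#' @param trim_fraction,sigma_factor threshold rule parameters.
#' @return data.frame with one row per (residue, atom) in either table:
#'   `residue_id`, `atom_label`, `delta_H`, `delta_X`, `csp`,
#'   `comparable`, `significant`; attribute `threshold` holds the
#'   [significance_threshold()] result.
#' @export
csp_table <- function(cond1, cond2, nucleus = c("N", "C"),
                      weights = csp_weights(),
                      trim_fraction = 0.10, sigma_factor = 1.5) {
  nucleus <- match.arg(nucleus)
  key1 <- paste(cond1$residue, cond1$atom)
  key2 <- paste(cond2$residue, cond2$atom)
  keys <- union(key1, key2)
  rows <- lapply(keys, function(k) {
    i <- match(k, key1); j <- match(k, key2)
    if (is.na(i) || is.na(j)) {
      src <- if (is.na(i)) cond2[j, ] else cond1[i, ]
      return(data.frame(residue_id = src$residue, atom_label = src$atom,
                        delta_H = NA_real_, delta_X = NA_real_,
                        csp = NA_real_, comparable = FALSE))
    }
    r <- compute_csp(c(cond1$shift_H[i], cond2$shift_H[j]),
                     c(cond1$shift_X[i], cond2$shift_X[j]),
                     nucleus = nucleus, weights = weights,
                     residue_id = cond1$residue[i],
                     atom_label = cond1$atom[i])
    data.frame(residue_id = r$residue_id, atom_label = r$atom_label,
               delta_H = r$delta_H, delta_X = r$delta_X, csp = r$csp,
               comparable = TRUE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$residue_id, out$atom_label), ]
  rownames(out) <- NULL
  thr <- significance_threshold(
    setNames(out$csp, out$residue_id)[out$comparable],
    trim_fraction = trim_fraction, sigma_factor = sigma_factor)
  out$significant <- out$comparable & out$csp > thr$threshold
  attr(out, "threshold") <- thr
  out
}

# --- 2D Lorentzian peak cluster deconvolution -------------------------------

# Model for one component on grid (x = direct/1H ppm, y = indirect ppm):
#   A / ((1 + ((x-x0)/wx)^2) * (1 + ((y-y0)/wy)^2))
# with half-widths-at-half-maximum wx, wy.  Analytic volume = A*pi^2*wx*wy.
lorentz2d <- function(x, y, x0, y0, wx, wy, A) {
  A / ((1 + ((x - x0) / wx)^2) %o% (1 + ((y - y0) / wy)^2))
}

#' Quantify fractional state populations in an overlapped peak cluster
#'
#' Fits `n_states` two-dimensional Lorentzian components (position, two
#' half-widths, amplitude each) to an intensity grid by
#' Levenberg-Marquardt least squares and reports each state's fractional
#' population as its share of the total fitted volume
#' (volume = amplitude * pi^2 * wx * wy).  Overlapped peaks bias raw
#' heights, so volumes are the default; `mode = "height"` reports
#' height-share instead.
#'
#' @param grid list with `x` (ppm, direct dimension), `y` (ppm, indirect),
#'   and `z` (intensity matrix, `length(x)` rows by `length(y)` columns),
#'   as produced by [gen_peak_cluster()].
#' @param n_states number of components (>= 1).
#' @param init_positions matrix/list of starting `(x, y)` positions, one
#'   per state; required for `n_states > 1`.
#' @param init_linewidth starting half-width (ppm) for both dimensions;
#'   a vector of two gives `(wx, wy)`.
#' @param mode `"volume"` (default) or `"height"`.
#' @return `peak_cluster` list: `populations` (sorted by component order),
#'   `positions`, `linewidths`, `amplitudes`, `volumes`, `converged`.
#' @export
quantify_populations <- function(grid, n_states, init_positions = NULL,
                                 init_linewidth = c(0.02, 0.2),
                                 mode = c("volume", "height")) {
  mode <- match.arg(mode)
  stopifnot(n_states >= 1, is.matrix(grid$z),
            nrow(grid$z) == length(grid$x), ncol(grid$z) == length(grid$y))
  if (is.null(init_positions)) {
    if (n_states > 1)
      stop("init_positions must be supplied when n_states > 1")
    ij <- which(grid$z == max(grid$z), arr.ind = TRUE)[1, ]
    init_positions <- matrix(c(grid$x[ij[1]], grid$y[ij[2]]), 1)
  }
  init_positions <- matrix(unlist(init_positions), ncol = 2,
                           byrow = !is.matrix(init_positions))
  stopifnot(nrow(init_positions) == n_states)
  rng_ok <- all(init_positions[, 1] >= min(grid$x), init_positions[, 1] <= max(grid$x),
                init_positions[, 2] >= min(grid$y), init_positions[, 2] <= max(grid$y))
  if (!rng_ok) stop("initial positions fall outside the grid")
  lw <- rep_len(init_linewidth, 2)
  amp0 <- max(grid$z) / n_states
  # parameters per state: x0, y0, log(wx), log(wy), amplitude
  par0 <- as.vector(t(cbind(init_positions, log(lw[1]), log(lw[2]), amp0)))
  model <- function(p) {
    z <- 0
    for (s in seq_len(n_states)) {
      q <- p[(5 * (s - 1) + 1):(5 * s)]
      z <- z + lorentz2d(grid$x, grid$y, q[1], q[2], exp(q[3]), exp(q[4]), q[5])
    }
    z
  }
  fit <- minpack.lm::nls.lm(par0, fn = function(p) as.vector(grid$z - model(p)),
                            control = minpack.lm::nls.lm.control(maxiter = 400))
  if (fit$info %in% c(0, 5, 9))
    stop("lineshape fit did not converge: ", fit$message)
  p <- matrix(coef(fit), ncol = 5, byrow = TRUE)
  amps <- p[, 5]
  if (any(amps < 0))
    stop("lineshape fit produced a negative component amplitude; ",
         "check n_states and initial positions")
  wx <- exp(p[, 3]); wy <- exp(p[, 4])
  vols <- amps * pi^2 * wx * wy
  share <- if (mode == "volume") vols else amps
  structure(list(populations = share / sum(share),
                 positions = p[, 1:2, drop = FALSE],
                 linewidths = cbind(wx = wx, wy = wy),
                 amplitudes = amps, volumes = vols,
                 mode = mode, converged = TRUE),
            class = "peak_cluster")
}
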