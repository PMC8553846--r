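# Internal helpers shared across modules.

# Gyromagnetic ratios (10^7 rad s^-1 T^-1, CODATA-style values used
# throughout biomolecular NMR).
.GAMMA <- c(H = 26.7522128, N = -2.7126180, C = 6.728284)

#' Nucleus weighting factors for chemical shift perturbations
#'
#' Computes the per-nucleus weights |gamma_X / gamma_H| used in the weighted
#' CSP formula, truncated (not rounded) to three decimals, which yields the
#' conventional W_N = 0.101 and W_C = 0.251.
#'
#' @param digits number of decimals to truncate to (default 3).
#' @return named numeric vector with elements `N` and `C`.
#' @examples
#' csp_weights_from_gamma()
#' @export
csp_weights_from_gamma <- function(digits = 3) {
  w <- abs(.GAMMA[c("N", "C")] / .GAMMA[["H"]])
  trunc(w * 10^digits) / 10^digits
}

#' Default CSP weights
#'
#' @param W_N weight for 15N shift differences.
#' @param W_C weight for 13C shift differences.
#' @return object of class `csp_weights`.
#' @export
csp_weights <- function(W_N = 0.101, W_C = 0.251) {
  stopifnot(W_N > 0, W_N < 1, W_C > 0, W_C < 1)
  structure(list(W_N = W_N, W_C = W_C), class = "csp_weights")
}

# Derive an independent random substream from (seed, label) so that adding a
# generator never perturbs the draws of existing ones.  A small polynomial
# hash of the label keeps the combined seed inside 32-bit integer range.
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- 0
  for (k in utf8ToInt(as.character(label))) h <- (h * 31 + k) %% 1000003L
  as.integer((abs(seed) %% 1009L) * 1000003 + h) %% 2100000000L
}

with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, label))
  force(expr)
}

#' Apply the peak-height error floor
#'
#' Measured base-plane noise occasionally underestimates the true intensity
#' uncertainty; a fractional floor (2\% of the peak height by default) is
#' imposed wherever the stated error is absent or smaller.
#'
#' @param height peak heights.
#' @param error stated errors, or `NA` where none were given.
#' @param floor fractional floor (default 0.02).
#' @return numeric vector of floored errors.
#' @export
apply_error_floor <- function(height, error = NA_real_, floor = 0.02) {
  stopifnot(floor >= 0)
  error <- rep_len(as.numeric(error), length(height))
  pmax(ifelse(is.na(error), 0, error), floor * abs(height))
}

# Exact exponential of a 2x2 complex matrix given as four scalars
# (a b / c d), via the closed form
#   expm(A) = e^mu (cosh(q) I + sinh(q)/q (A - mu I)),  q^2 = (a-d)^2/4 + bc.
# Returns the four entries of the exponential.  Used by the CPMG
# propagators, where it is called many times on tiny matrices.
expm2 <- function(a, b, c, d) {
  mu <- (a + d) / 2
  q2 <- (a - d)^2 / 4 + b * c
  q <- sqrt(q2)
  if (abs(q) < 1e-12) {
    e <- exp(mu)
    ch <- e * (1 + q2 / 2)
    shq <- e * (1 + q2 / 6)     # e^mu * sinh(q)/q ~ e^mu (1 + q^2/6)
  } else {
    # e^mu cosh(q) and e^mu sinh(q)/q via e^(mu+q), e^(mu-q): for decaying
    # generators mu +- q stays bounded, avoiding cosh overflow at large kex
    e1 <- exp(mu + q); e2 <- exp(mu - q)
    ch <- (e1 + e2) / 2
    shq <- (e1 - e2) / (2 * q)
  }
  list(
    a = ch + shq * (a - d) / 2,
    b = shq * b,
    c = shq * c,
    d = ch - shq * (a - d) / 2
  )
}

# Multiply two 2x2 matrices stored as lists of scalars.
mat2mul <- function(x, y) {
  list(
    a = x$a * y$a + x$b * y$c,
    b = x$a * y$b + x$b * y$d,
    c = x$c * y$a + x$d * y$c,
    d = x$c * y$b + x$d * y$d
  )
}

# x^n by repeated squaring for 2x2 matrices in the same representation.
mat2pow <- function(x, n) {
  out <- list(a = 1 + 0i, b = 0i, c = 0i, d = 1 + 0i)
  while (n > 0) {
    if (n %% 2 == 1) out <- mat2mul(out, x)
    x <- mat2mul(x, x)
    n <- n %/% 2
  }
  out
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
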