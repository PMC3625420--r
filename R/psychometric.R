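#' Psychometric parameter set
#'
#' Bundles the three parameters of the Weibull psychometric function for a
#' two-alternative choice task: the threshold `m` (the relative intensity at
#' which performance lies halfway between the chance level 0.5 and the upper
#' asymptote), the slope `s` of the curve at the threshold, and the lapse rate
#' `lapse` (the probability of a choice made independently of the stimulus,
#' e.g. through exploration). The upper asymptote of the implied curve is
#' `1 - lapse/2`; the lower asymptote is the 2-AFC chance level 0.5.
#'
#' @param threshold Threshold `m`, in relative-intensity units; must be > 0.
#' @param slope Slope `s` of the curve at the threshold; must be > 0.
#' @param lapse Lapse rate in `[0, 1)`.
#' @return An object of class `psy_params`: a named list with elements
#'   `threshold`, `slope` and `lapse`.
#' @examples
#' psy_params(threshold = 0.251, slope = 5.30, lapse = 0.23)
#' @export
psy_params <- function(threshold, slope, lapse = 0) {
  check_number(threshold, "threshold", lower = 0, open_lower = TRUE)
  check_number(slope, "slope", lower = 0, open_lower = TRUE)
  check_number(lapse, "lapse", lower = 0, upper = 1, open_upper = TRUE)
  structure(list(threshold = threshold, slope = slope, lapse = lapse),
            class = "psy_params")
}

#' @export
print.psy_params <- function(x, ...) {
  cat(sprintf(
    "<psy_params> threshold = %g, slope = %g, lapse = %g (upper asymptote %.3f)\n",
    x$threshold, x$slope, x$lapse, 1 - x$lapse / 2))
  invisible(x)
}

as_psy_params <- function(x) {
  if (inherits(x, "psy_params")) return(x)
  if (is.numeric(x) && !is.null(names(x))) x <- as.list(x)
  if (is.list(x) && all(c("threshold", "slope", "lapse") %in% names(x))) {
    return(psy_params(x$threshold, x$slope, x$lapse))
  }
  abort("`params` must be a psy_params object or a named list/vector with threshold, slope, lapse.")
}

# Argument of the double exponential, clamped to +/- 700 so exp() never
# overflows; the clamp only engages where the curve is already flat at an
# asymptote to double precision.
psy_linpred <- function(x, threshold, slope) {
  a <- (2 * slope * threshold / log(2)) * (log(x) - log(threshold)) + log(log(2))
  pmin(pmax(a, -700), 700)
}

#' Weibull psychometric function for two-alternative choice
#'
#' Evaluates the probability of choosing the higher-intensity (sweeter) option
#' at relative stimulus intensity `x`:
#' \deqn{\Psi(x) = \tfrac{1}{2}\left[\pi_l + (1-\pi_l)\left[2 -
#'   \exp\!\big(-\exp\big(\tfrac{2sm}{\ln 2}(\ln x - \ln m) +
#'   \ln\ln 2\big)\big)\right]\right]}
#' in the Kuss-style parameterization: `m` is the threshold, `s` the slope at
#' the threshold and `pi_l` the lapse rate. The curve rises strictly from the
#' chance level 0.5 (as `x -> 0`) to the upper asymptote `1 - pi_l/2`
#' (as `x -> Inf`), and `psy_fun(m) = 0.75 - 0.25 * pi_l`.
#'
#' @param x Relative intensity, > 0. Vectorized.
#' @param params A [psy_params()] object (or coercible named list).
#' @return Choice probabilities in `(0.5, 1 - lapse/2)`.
#' @examples
#' psy_fun(0.30, psy_params(0.251, 5.30, 0.23))
#' psy_fun(0.25, psy_params(0.25, 5, 0))  # exactly 0.75 at threshold
#' @seealso [psy_inverse()], [lapse_from_upper_asymptote()]
#' @export
psy_fun <- function(x, params) {
  params <- as_psy_params(params)
  check_positive_vector(x, "x")
  a <- psy_linpred(x, params$threshold, params$slope)
  0.5 * (params$lapse + (1 - params$lapse) * (2 - exp(-exp(a))))
}

#' Inverse of the psychometric function
#'
#' Finds the relative intensity at which the psychometric curve attains a given
#' choice probability, by monotone bisection on `log x` (with bracket
#' expansion), exploiting strict monotonicity of the curve.
#'
#' @param p Target probability, strictly between 0.5 and the upper asymptote
#'   `1 - lapse/2`. Vectorized.
#' @param params A [psy_params()] object.
#' @param tol Absolute tolerance on the probability scale (default `1e-9`).
#' @return Relative intensities `x` with `psy_fun(x, params) == p` to `tol`.
#' @examples
#' psy_inverse(0.75, psy_params(0.25, 5, 0))  # the threshold itself
#' @export
psy_inverse <- function(p, params, tol = 1e-9) {
  params <- as_psy_params(params)
  upper <- 1 - params$lapse / 2
  if (any(!is.finite(p)) || any(p <= 0.5) || any(p >= upper)) {
    abort(sprintf("`p` must lie strictly between 0.5 and the upper asymptote %g.", upper))
  }
  vapply(p, function(pi) {
    lo <- log(params$threshold); hi <- lo
    while (psy_fun(exp(lo), params) > pi) lo <- lo - 1
    while (psy_fun(exp(hi), params) < pi) hi <- hi + 1
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (psy_fun(exp(mid), params) < pi) lo <- mid else hi <- mid
      if (abs(psy_fun(exp(mid), params) - pi) < tol) break
    }
    exp((lo + hi) / 2)
  }, numeric(1))
}

#' Lapse rate from the upper asymptote
#'
#' A lapsing forager chooses at the 0.5 chance level, so half of its lapses
#' land on the wrong option and the upper asymptote of the psychometric curve
#' is depressed to `1 - lapse/2`. This inverts that relation:
#' `lapse = 2 * (1 - upper)`.
#'
#' @param upper Upper asymptote, in `(0.5, 1]`. Vectorized.
#' @return Lapse rate(s) in `[0, 1)`.
#' @examples
#' lapse_from_upper_asymptote(0.885)  # 0.23
#' @export
lapse_from_upper_asymptote <- function(upper) {
  if (any(!is.finite(upper)) || any(upper <= 0.5) || any(upper > 1)) {
    abort("`upper` must lie in (0.5, 1].")
  }
  2 * (1 - upper)
}

# ---- validation helpers ----

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number in %s%g, %g%s.",
                  name, if (open_lower) "(" else "[", lower, upper,
                  if (open_upper) ")" else "]"))
  }
  invisible(x)
}

check_positive_vector <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be finite and strictly positive.", name))
  }
  invisible(x)
}
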