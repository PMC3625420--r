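#' Prior specification for psychometric fitting
#'
#' Priors on the three psychometric parameters: truncated-normal (at zero)
#' priors on threshold and slope and a beta prior on the lapse rate. The
#' defaults are the study priors: threshold ~ N(1, 0.5) truncated to (0, Inf),
#' slope ~ N(2, 1) truncated to (0, Inf), and lapse ~ Beta(2, 20) — a lapse
#' prior deliberately wider than the 0.01–0.10 range typical of human work,
#' to admit the higher lapse rates produced by exploratory foraging.
#'
#' The slope prior may instead be flat (improper uniform on `(0, slope_max]`),
#' as used in the pooling-bias simulation to remove prior shrinkage of the
#' slope; see [flat_slope_priors()].
#'
#' Truncation renormalization constants are omitted throughout: they shift the
#' log-posterior by a constant and leave the posterior shape unchanged.
#'
#' @param threshold_mean,threshold_sd Mean and SD of the normal prior on the
#'   threshold (truncated to positive values).
#' @param slope_mean,slope_sd Mean and SD of the normal prior on the slope
#'   (truncated to positive values). Ignored when `slope_flat = TRUE`.
#' @param lapse_shape1,lapse_shape2 Shape parameters of the beta prior on the
#'   lapse rate.
#' @param slope_flat If `TRUE`, use a flat slope prior on `(0, slope_max]`.
#' @param slope_max Upper bound of the flat slope prior (kept finite so the
#'   grid-integration oracle has a bounded domain; far above plausible slopes).
#' @return An object of class `psy_priors`.
#' @examples
#' default_priors()
#' flat_slope_priors()
#' @export
prior_spec <- function(threshold_mean = 1, threshold_sd = 0.5,
                       slope_mean = 2, slope_sd = 1,
                       lapse_shape1 = 2, lapse_shape2 = 20,
                       slope_flat = FALSE, slope_max = 50) {
  check_number(threshold_sd, "threshold_sd", lower = 0, open_lower = TRUE)
  check_number(slope_sd, "slope_sd", lower = 0, open_lower = TRUE)
  check_number(lapse_shape1, "lapse_shape1", lower = 0, open_lower = TRUE)
  check_number(lapse_shape2, "lapse_shape2", lower = 0, open_lower = TRUE)
  check_number(slope_max, "slope_max", lower = 0, open_lower = TRUE)
  structure(list(threshold_mean = threshold_mean, threshold_sd = threshold_sd,
                 slope_mean = slope_mean, slope_sd = slope_sd,
                 lapse_shape1 = lapse_shape1, lapse_shape2 = lapse_shape2,
                 slope_flat = isTRUE(slope_flat), slope_max = slope_max),
            class = "psy_priors")
}

#' @rdname prior_spec
#' @export
default_priors <- function() prior_spec()

#' @rdname prior_spec
#' @export
flat_slope_priors <- function(slope_max = 50) prior_spec(slope_flat = TRUE, slope_max = slope_max)

#' @export
print.psy_priors <- function(x, ...) {
  slope <- if (x$slope_flat) sprintf("flat on (0, %g]", x$slope_max) else
    sprintf("N(%g, %g) truncated > 0", x$slope_mean, x$slope_sd)
  cat(sprintf(paste0(
    "<psy_priors>\n  threshold: N(%g, %g) truncated > 0\n",
    "  slope:     %s\n  lapse:     Beta(%g, %g)\n"),
    x$threshold_mean, x$threshold_sd, slope, x$lapse_shape1, x$lapse_shape2))
  invisible(x)
}

# Log prior density on the natural scale (unnormalized under truncation).
log_prior <- function(threshold, slope, lapse, priors) {
  if (threshold <= 0 || slope <= 0 || lapse < 0 || lapse >= 1) return(-Inf)
  lp <- dnorm(threshold, priors$threshold_mean, priors$threshold_sd, log = TRUE) +
    dbeta(lapse, priors$lapse_shape1, priors$lapse_shape2, log = TRUE)
  lp + if (priors$slope_flat) {
    if (slope > priors$slope_max) -Inf else 0
  } else {
    dnorm(slope, priors$slope_mean, priors$slope_sd, log = TRUE)
  }
}
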