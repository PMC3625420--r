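# Validation of binomial response records: one row per stimulus condition
# with columns intensity (> 0), n_sweeter (visits to the sweeter option) and
# n_total. Zero rows are allowed and yield a prior-only posterior.
validate_records <- function(data, call_name = "data") {
  if (!is.data.frame(data)) abort(sprintf("`%s` must be a data frame.", call_name))
  need <- c("intensity", "n_sweeter", "n_total")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(sprintf("`%s` is missing column(s): %s.", call_name,
                  paste(miss, collapse = ", ")))
  }
  if (nrow(data) == 0L) return(tibble::as_tibble(data[need]))
  with(data, {
    if (any(!is.finite(intensity)) || any(intensity <= 0)) {
      abort("`intensity` must be finite and > 0 for fitting (drop zero-intensity conditions first).")
    }
    if (any(n_total <= 0) || any(n_sweeter < 0) || any(n_sweeter > n_total)) {
      abort("counts must satisfy 0 <= n_sweeter <= n_total with n_total > 0.")
    }
  })
  tibble::as_tibble(data[need])
}

#' Log-posterior density of psychometric parameters
#'
#' Binomial log-likelihood of the choice counts under the Weibull psychometric
#' function plus the log prior densities. Parameters outside the prior support
#' (non-positive threshold or slope, lapse outside `[0, 1)`, slope above a flat
#' prior's bound) return `-Inf` rather than raising an error.
#'
#' @param params A [psy_params()] object or named list with `threshold`,
#'   `slope`, `lapse`.
#' @param data Data frame of response records with columns `intensity`,
#'   `n_sweeter`, `n_total`. May have zero rows (prior-only density).
#' @param priors A [prior_spec()] object.
#' @return A single log density (up to the truncation constant); `-Inf`
#'   outside the support.
#' @examples
#' recs <- tibble::tibble(intensity = 1, n_sweeter = 0, n_total = 1)
#' log_posterior(list(threshold = 1, slope = 2, lapse = 0.1), recs)
#' @export
log_posterior <- function(params, data, priors = default_priors()) {
  if (!is.list(params) && !(is.numeric(params) && !is.null(names(params)))) {
    abort("`params` must be a psy_params object or named list/vector.")
  }
  p <- as.list(params)
  th <- p$threshold; sl <- p$slope; la <- p$lapse
  if (!is.finite(th) || !is.finite(sl) || !is.finite(la)) return(-Inf)
  lp <- log_prior(th, sl, la, priors)
  if (!is.finite(lp)) return(-Inf)
  data <- validate_records(data)
  if (nrow(data) == 0L) return(lp)
  psi <- psy_fun(data$intensity, psy_params(th, sl, la))
  lp + sum(data$n_sweeter * log(psi) + (data$n_total - data$n_sweeter) * log1p(-psi))
}

# Log-posterior on the unconstrained sampling scale
# theta = (log m, log s, logit lapse), with change-of-variable Jacobians.
log_posterior_theta <- function(theta, data, priors) {
  m <- exp(theta[1]); s <- exp(theta[2]); la <- plogis(theta[3])
  lp <- log_prior(m, s, la, priors)
  if (!is.finite(lp)) return(-Inf)
  if (nrow(data) > 0L) {
    a <- psy_linpred(data$intensity, m, s)
    psi <- 0.5 * (la + (1 - la) * (2 - exp(-exp(a))))
    lp <- lp + sum(data$n_sweeter * log(psi) + (data$n_total - data$n_sweeter) * log1p(-psi))
  }
  # Jacobians: dm/dtheta1 = m, ds/dtheta2 = s, dlapse/dtheta3 = lapse(1-lapse)
  lp + theta[1] + theta[2] + log(la) + log1p(-la)
}
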