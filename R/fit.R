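#' Bayesian psychometric fit by adaptive Metropolis sampling
#'
#' Samples the joint posterior of threshold, slope and lapse rate given
#' binomial choice counts, using a random-walk Metropolis chain on the
#' unconstrained scale `(log m, log s, logit lapse)`. The chain starts at the
#' posterior mode (found with [stats::optim()]) and proposes from a
#' multivariate normal whose covariance is the Laplace approximation
#' (scaled inverse Hessian), with the global step size adapted during burn-in
#' toward an acceptance rate of about 0.3 and then frozen, so retained draws
#' come from a fixed Markov kernel.
#'
#' Draws, posterior means and central 95% credible intervals are returned on
#' the natural parameter scale. With a seed the draw sequence is exactly
#' reproducible. Zero-row `data` yields a prior-only posterior, which is
#' useful for prior-recovery checks.
#'
#' @param data Data frame of response records: columns `intensity` (> 0),
#'   `n_sweeter`, `n_total`. Fewer than 3 distinct intensities triggers a
#'   warning (the three-parameter curve is then weakly identified).
#' @param priors A [prior_spec()] object.
#' @param n_draws Number of retained posterior draws (default 5000).
#' @param burn_in Number of initial adaptation iterations discarded before
#'   retention; default 20% of the total chain length.
#' @param seed Optional integer seed for exact reproducibility.
#' @return An object of class `psy_fit` with elements `draws` (tibble of
#'   retained draws), `summary` (tibble: term, estimate, std.error, conf.low,
#'   conf.high, ess), `map` (posterior mode as [psy_params()]), `diagnostics`
#'   (acceptance rate, effective sample sizes, prior-dominance flag), plus the
#'   data, priors and configuration. Supports [tidy()], [glance()],
#'   [autoplot()] and `print()`.
#' @examples
#' recs <- simulate_binomial_responses(psy_params(0.25, 5, 0.15),
#'                                     intensities = c(0.1, 0.25, 0.5),
#'                                     n_per = 200, seed = 1)
#' fit <- fit_psychometric(recs, n_draws = 1000, seed = 1)
#' tidy(fit)
#' @export
fit_psychometric <- function(data, priors = default_priors(),
                             n_draws = 5000, burn_in = ceiling(n_draws / 4),
                             seed = NULL) {
  data <- validate_records(data)
  priors <- stopifnot_priors(priors)
  check_number(n_draws, "n_draws", lower = 1)
  check_number(burn_in, "burn_in", lower = 0)
  n_int <- dplyr::n_distinct(data$intensity)
  if (nrow(data) > 0L && n_int < 3) {
    warn(sprintf("only %d distinct intensit%s: the three-parameter fit is weakly identified.",
                 n_int, if (n_int == 1) "y" else "ies"))
  }
  run <- function() metropolis_psy(data, priors, n_draws, burn_in)
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  draws <- res$draws
  summ <- summarize_draws(draws, res$ess)
  post_sd_thr <- summ$std.error[summ$term == "threshold"]
  diagnostics <- list(
    acceptance_rate = res$acceptance_rate,
    ess = res$ess,
    n_intensities = n_int,
    prior_dominated = is.finite(post_sd_thr) && post_sd_thr > 0.7 * priors$threshold_sd
  )
  structure(list(draws = draws, summary = summ, map = res$map,
                 diagnostics = diagnostics, data = data, priors = priors,
                 n_draws = n_draws, burn_in = burn_in, seed = seed),
            class = "psy_fit")
}

stopifnot_priors <- function(priors) {
  if (!inherits(priors, "psy_priors")) abort("`priors` must be created with prior_spec().")
  priors
}

# Core sampler. Assumes the RNG state is already set by the caller.
metropolis_psy <- function(data, priors, n_draws, burn_in) {
  target <- function(theta) log_posterior_theta(theta, data, priors)
  starts <- list(c(log(priors$threshold_mean), log(if (priors$slope_flat) 3 else priors$slope_mean),
                   qlogis(priors$lapse_shape1 / (priors$lapse_shape1 + priors$lapse_shape2))))
  if (nrow(data) > 0L) starts <- c(starts, list(c(log(0.3), log(3), qlogis(0.15))))
  opt <- NULL
  for (st in starts) {
    o <- tryCatch(optim(st, target, control = list(fnscale = -1, maxit = 500),
                        method = "BFGS", hessian = TRUE),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(opt) || o$value > opt$value)) opt <- o
  }
  if (is.null(opt)) abort("posterior mode search failed; check the data and priors.")
  sigma <- tryCatch(solve(-opt$hessian), error = function(e) NULL)
  if (is.null(sigma) || any(!is.finite(sigma)) || any(diag(sigma) <= 0)) {
    sigma <- diag(0.1, 3)
  }
  prop_chol <- tryCatch(chol((2.38^2 / 3) * sigma),
                        error = function(e) chol(diag((2.38^2 / 3) * pmax(diag(sigma), 1e-6))))

  theta <- opt$par
  l_cur <- target(theta)
  total <- burn_in + n_draws
  keep <- matrix(NA_real_, n_draws, 3)
  scale <- 1
  acc_batch <- 0L; acc_keep <- 0L; batch <- 0L
  for (i in seq_len(total)) {
    prop <- theta + scale * drop(rnorm(3) %*% prop_chol)
    l_prop <- target(prop)
    if (is.finite(l_prop) && log(runif(1)) < l_prop - l_cur) {
      theta <- prop; l_cur <- l_prop
      if (i <= burn_in) acc_batch <- acc_batch + 1L else acc_keep <- acc_keep + 1L
    }
    if (i <= burn_in && i %% 50 == 0) {
      batch <- batch + 1L
      scale <- scale * exp((acc_batch / 50 - 0.3) / sqrt(batch))
      acc_batch <- 0L
    }
    if (i > burn_in) keep[i - burn_in, ] <- theta
  }
  draws <- tibble::tibble(threshold = exp(keep[, 1]), slope = exp(keep[, 2]),
                          lapse = plogis(keep[, 3]))
  ess <- vapply(draws, function(v) unname(coda::effectiveSize(v)), numeric(1))
  list(draws = draws,
       acceptance_rate = acc_keep / n_draws,
       ess = ess,
       map = psy_params(exp(opt$par[1]), exp(opt$par[2]), plogis(opt$par[3])))
}

summarize_draws <- function(draws, ess = NULL) {
  tibble::tibble(
    term = names(draws),
    estimate = vapply(draws, mean, numeric(1)),
    std.error = vapply(draws, sd, numeric(1)),
    conf.low = vapply(draws, quantile, numeric(1), probs = 0.025, names = FALSE),
    conf.high = vapply(draws, quantile, numeric(1), probs = 0.975, names = FALSE),
    ess = if (is.null(ess)) NA_real_ else unname(ess[names(draws)])
  )
}

#' @export
print.psy_fit <- function(x, ...) {
  cat(sprintf("<psy_fit> %d records, %d retained draws (acceptance %.2f)\n",
              nrow(x$data), nrow(x$draws), x$diagnostics$acceptance_rate))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  if (x$diagnostics$prior_dominated) {
    cat("note: posterior is close to the prior (weak data).\n")
  }
  invisible(x)
}

#' @rdname fit_psychometric
#' @param x,object A `psy_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.psy_fit <- function(x, ...) x$summary

#' @rdname fit_psychometric
#' @exportS3Method generics::glance
glance.psy_fit <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x$data),
    n_visits = sum(x$data$n_total),
    n_draws = nrow(x$draws),
    acceptance_rate = x$diagnostics$acceptance_rate,
    min_ess = if (length(x$diagnostics$ess)) min(x$diagnostics$ess) else NA_real_,
    prior_dominated = x$diagnostics$prior_dominated
  )
}

#' @rdname fit_psychometric
#' @param n_curve Number of abscissa points for the fitted curve.
#' @exportS3Method ggplot2::autoplot
autoplot.psy_fit <- function(object, n_curve = 200, ...) {
  est <- setNames(object$summary$estimate, object$summary$term)
  xr <- if (nrow(object$data)) range(object$data$intensity) else c(0.02, 1)
  xs <- exp(seq(log(xr[1] / 2), log(xr[2] * 1.2), length.out = n_curve))
  pars <- psy_params(est["threshold"], est["slope"], est["lapse"])
  band <- posterior_curve_band(object$draws, xs)
  curve_df <- tibble::tibble(intensity = xs, response = psy_fun(xs, pars),
                             lo = band$lo, hi = band$hi)
  p <- ggplot2::ggplot(curve_df, ggplot2::aes(x = .data$intensity, y = .data$response)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80", alpha = 0.7) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = est["threshold"], linetype = "dashed") +
    ggplot2::labs(x = "relative intensity", y = "proportion of visits to sweeter option") +
    ggplot2::coord_cartesian(ylim = c(0.4, 1))
  if (nrow(object$data)) {
    pts <- dplyr::mutate(object$data, response = .data$n_sweeter / .data$n_total)
    p <- p + ggplot2::geom_point(data = pts,
                                 ggplot2::aes(size = .data$n_total), alpha = 0.7) +
      ggplot2::scale_size_area(max_size = 4, guide = "none")
  }
  p
}

posterior_curve_band <- function(draws, xs, n_sub = 400) {
  idx <- if (nrow(draws) > n_sub) round(seq(1, nrow(draws), length.out = n_sub)) else seq_len(nrow(draws))
  mat <- vapply(idx, function(i) {
    psy_fun(xs, psy_params(draws$threshold[i], draws$slope[i], draws$lapse[i]))
  }, numeric(length(xs)))
  list(lo = apply(mat, 1, quantile, probs = 0.025),
       hi = apply(mat, 1, quantile, probs = 0.975))
}
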