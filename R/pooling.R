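#' Configuration for the data-pooling slope-bias experiment
#'
#' Sets up the simulation demonstrating that averaging choice data across
#' individuals with heterogeneous thresholds biases the fitted psychometric
#' slope downward while leaving threshold and lapse essentially unbiased:
#' several "individuals" share a common slope and lapse but differ in
#' threshold; their noise-free predicted performances are averaged at a fixed
#' set of intensities and refit as if they came from one animal.
#'
#' By default the individual thresholds are a fixed, symmetric, evenly spaced
#' set rescaled to the target mean and SD — deterministic, so the experiment
#' is exactly reproducible; pass `thresholds` to use any other set (e.g. a
#' normal draw).
#'
#' @param n_individuals Number of simulated individuals (default 7).
#' @param threshold_mean,threshold_sd Mean and SD of the individual
#'   thresholds (defaults 0.25 and 0.057).
#' @param slope,lapse Common slope (5) and lapse rate (0.15).
#' @param intensities Relative intensities probed (defaults 0.05, 0.15, 0.25,
#'   0.3, 0.4, 0.5, 0.6).
#' @param visits_per_individual Visits per individual per intensity (200).
#' @param thresholds Optional explicit threshold vector overriding the
#'   deterministic construction.
#' @param sample_counts If `TRUE`, draw each individual's visits binomially
#'   instead of using noise-free expected counts (default `FALSE`: the pooled
#'   response at each intensity is then exactly the mean of the individual
#'   curve values).
#' @param slope_max Upper bound of the flat slope prior used in the refit.
#' @return An object of class `pooling_config`.
#' @export
pooling_config <- function(n_individuals = 7, threshold_mean = 0.25,
                           threshold_sd = 0.057, slope = 5, lapse = 0.15,
                           intensities = c(0.05, 0.15, 0.25, 0.3, 0.4, 0.5, 0.6),
                           visits_per_individual = 200, thresholds = NULL,
                           sample_counts = FALSE, slope_max = 50) {
  check_number(n_individuals, "n_individuals", lower = 1)
  check_positive_vector(intensities, "intensities")
  check_number(visits_per_individual, "visits_per_individual", lower = 1)
  if (is.null(thresholds)) {
    thresholds <- even_thresholds(n_individuals, threshold_mean, threshold_sd)
  }
  check_positive_vector(thresholds, "thresholds")
  if (length(thresholds) != n_individuals) {
    abort("`thresholds` must have length `n_individuals`.")
  }
  structure(list(n_individuals = n_individuals, thresholds = thresholds,
                 slope = slope, lapse = lapse, intensities = intensities,
                 visits_per_individual = visits_per_individual,
                 sample_counts = isTRUE(sample_counts), slope_max = slope_max),
            class = "pooling_config")
}

# Symmetric evenly spaced point set rescaled to an exact mean and SD.
even_thresholds <- function(n, mean, sd) {
  if (n == 1) return(mean)
  z <- seq(-1, 1, length.out = n)
  mean + z * sd / stats::sd(z)
}

#' Run the pooling slope-bias experiment
#'
#' Computes each individual's predicted performance at the configured
#' intensities, pools them into one binomial record per intensity
#' (`n_total = visits_per_individual * n_individuals`, response equal to the
#' across-individual mean performance), and refits the psychometric function
#' with a flat slope prior (all other priors as in the main analysis, per
#' `priors`). Heterogeneous thresholds make the pooled curve shallower than
#' any individual curve, so the refit slope falls below the common true
#' slope; the threshold and lapse estimates remain close to the individual
#' averages. The curve built from the across-individual parameter means is
#' returned for comparison.
#'
#' @param config A [pooling_config()] object.
#' @param priors Priors for the refit; defaults to the standard priors with
#'   the slope prior flattened on `(0, slope_max]`.
#' @param n_draws,burn_in Chain lengths passed to [fit_psychometric()].
#' @param seed Optional integer seed covering both count sampling (when
#'   `sample_counts = TRUE`) and the Metropolis chain.
#' @return An object of class `pooling_experiment`: list with `individuals`
#'   (tibble of true per-individual parameters), `pooled_records` (fit-ready
#'   response records), `fit` (the [fit_psychometric()] result),
#'   `averaged_params` (a [psy_params()] from across-individual means) and
#'   `config`. Supports [tidy()], [glance()], [autoplot()] and `print()`.
#' @examples
#' exp <- run_pooling_experiment(n_draws = 800, seed = 1)
#' tidy(exp)  # fitted slope below the true common slope of 5
#' @export
run_pooling_experiment <- function(config = pooling_config(),
                                   priors = flat_slope_priors(config$slope_max),
                                   n_draws = 5000, burn_in = ceiling(n_draws / 4),
                                   seed = NULL) {
  if (!inherits(config, "pooling_config")) {
    abort("`config` must be created with pooling_config().")
  }
  run <- function() {
    individuals <- tibble::tibble(individual = seq_len(config$n_individuals),
                                  threshold = config$thresholds,
                                  slope = config$slope, lapse = config$lapse)
    psi <- vapply(config$intensities, function(x) {
      vapply(seq_len(config$n_individuals), function(i) {
        psy_fun(x, psy_params(individuals$threshold[i], config$slope, config$lapse))
      }, numeric(1))
    }, numeric(config$n_individuals))
    n_per <- config$visits_per_individual
    n_total <- n_per * config$n_individuals
    n_sweeter <- if (config$sample_counts) {
      apply(psi, 2, function(col) sum(rbinom(length(col), n_per, col)))
    } else {
      round(n_total * colMeans(psi))
    }
    records <- tibble::tibble(intensity = config$intensities,
                              n_sweeter = as.integer(n_sweeter),
                              n_total = as.integer(n_total))
    fit <- fit_psychometric(records, priors = priors, n_draws = n_draws,
                            burn_in = burn_in, seed = NULL)
    structure(list(individuals = individuals, pooled_records = records,
                   fit = fit,
                   averaged_params = psy_params(mean(config$thresholds),
                                                config$slope, config$lapse),
                   config = config),
              class = "pooling_experiment")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.pooling_experiment <- function(x, ...) {
  cat(sprintf("<pooling_experiment> %d individuals, true slope %g, thresholds %s\n",
              x$config$n_individuals, x$config$slope,
              paste(signif(x$config$thresholds, 3), collapse = ", ")))
  print(as.data.frame(x$fit$summary[, 1:5]), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @rdname run_pooling_experiment
#' @param x,object A `pooling_experiment` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pooling_experiment <- function(x, ...) tidy(x$fit)

#' @rdname run_pooling_experiment
#' @exportS3Method generics::glance
glance.pooling_experiment <- function(x, ...) {
  est <- setNames(x$fit$summary$estimate, x$fit$summary$term)
  tibble::tibble(true_slope = x$config$slope,
                 fitted_slope = unname(est["slope"]),
                 slope_bias = unname(est["slope"]) - x$config$slope,
                 fitted_threshold = unname(est["threshold"]),
                 fitted_lapse = unname(est["lapse"]))
}

#' @rdname run_pooling_experiment
#' @exportS3Method ggplot2::autoplot
autoplot.pooling_experiment <- function(object, ...) {
  xs <- exp(seq(log(min(object$config$intensities) / 2),
                log(max(object$config$intensities) * 1.2), length.out = 200))
  ind <- purrr::pmap_dfr(object$individuals, function(individual, threshold, slope, lapse) {
    tibble::tibble(individual = individual, intensity = xs,
                   response = psy_fun(xs, psy_params(threshold, slope, lapse)))
  })
  est <- setNames(object$fit$summary$estimate, object$fit$summary$term)
  comp <- dplyr::bind_rows(
    tibble::tibble(which = "pooled fit", intensity = xs,
                   response = psy_fun(xs, psy_params(est["threshold"], est["slope"], est["lapse"]))),
    tibble::tibble(which = "averaged parameters", intensity = xs,
                   response = psy_fun(xs, object$averaged_params)))
  pts <- dplyr::mutate(object$pooled_records, response = .data$n_sweeter / .data$n_total)
  ggplot2::ggplot(mapping = ggplot2::aes(x = .data$intensity, y = .data$response)) +
    ggplot2::geom_line(data = ind, ggplot2::aes(group = .data$individual),
                       color = "grey70") +
    ggplot2::geom_line(data = comp, ggplot2::aes(linetype = .data$which)) +
    ggplot2::geom_point(data = pts) +
    ggplot2::scale_linetype_manual(values = c("pooled fit" = "dashed",
                                              "averaged parameters" = "solid")) +
    ggplot2::labs(x = "relative intensity",
                  y = "proportion of visits to sweeter option",
                  linetype = NULL) +
    ggplot2::coord_cartesian(ylim = c(0.4, 1))
}
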