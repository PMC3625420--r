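#' Daily discrimination sessions of the two bumblebee colonies
#'
#' Per-day summary of the two-colony, two-alternative free-choice sucrose
#' discrimination experiment on a 20-feeder array (10 blue, 10 yellow): the
#' concentrations offered on each color, the derived relative intensity, the
#' number of marked bees passing the 800-visit plateau criterion and the
#' estimated number of unmarked foragers, visit totals after plateau
#' filtering (reconstructed from values reported in thousands), and the
#' discrimination responses (proportion of visits to the sweeter option) of
#' marked and pooled unmarked bees. `NA` marks days with no qualifying visits
#' (undefined response). Concentration pairs were presented on two
#' consecutive days with colors exchanged (reversal design).
#'
#' @return A tibble with columns `colony`, `day`, `conc_blue`, `conc_yellow`,
#'   `conc_mean`, `intensity`, `marked_bees`, `unmarked_bees`,
#'   `marked_visits`, `unmarked_visits`, `response_marked`,
#'   `response_unmarked`.
#' @examples
#' colony_days()
#' marked_unmarked_concordance(colony_days())
#' @export
colony_days <- function() {
  d <- tibble::tribble(
    ~colony, ~day, ~conc_blue, ~conc_yellow, ~marked_bees, ~unmarked_bees,
    ~marked_visits_k, ~unmarked_visits_k, ~response_marked, ~response_unmarked,
    1,  1, 30, 15, 0,  0,    NA,   NA,   NA,   NA,
    1,  2, 15, 30, 1,  5,  0.59, 0.90, 0.96, 0.98,
    1,  3, 45, 30, 1,  4,  1.04, 0.76, 0.87, 0.94,
    1,  4, 30, 45, 0,  6,    NA, 0.77,   NA, 0.95,
    1,  5, 30, 20, 0,  7,    NA, 0.94,   NA, 0.87,
    1,  6, 20, 30, 1,  9,  0.02, 1.52, 0.92, 0.88,
    1,  7, 45, 50, 1,  8,  1.90, 1.71, 0.71, 0.70,
    1,  8, 50, 45, 0,  9,    NA, 1.82,   NA, 0.62,
    1,  9, 35, 45, 0,  6,    NA, 0.86,   NA, 0.79,
    1, 10, 45, 35, 1,  9,  1.20, 1.85, 0.83, 0.80,
    1, 11, 30, 32, 1,  7,  0.11, 1.62, 0.45, 0.48,
    1, 12, 32, 30, 1,  9,  0.44, 1.50, 0.49, 0.46,
    1, 13, 40, 20, 2, 13,  3.01, 2.39, 0.89, 0.89,
    1, 14, 20, 40, 2, 12,  4.45, 1.98, 0.92, 0.90,
    1, 15, 35, 39, 2, 14,  1.49, 2.56, 0.83, 0.67,
    1, 16, 39, 35, 1, 17,  0.47, 3.12, 0.56, 0.63,
    2,  1, 50, 45, 5, 20,  3.35, 5.01, 0.52, 0.57,
    2,  2, 45, 50, 2, 10,  0.06, 2.40, 0.52, 0.57,
    2,  3, 45, 30, 0, 11,    NA, 2.73,   NA, 0.85,
    2,  4, 30, 45, 4,  9,  2.71, 2.13, 0.96, 0.92,
    2,  5, 25, 20, 3,  9,  1.20, 2.43, 0.54, 0.65,
    2,  6, 20, 25, 4, 11,  5.51, 2.40, 0.60, 0.62,
    2,  7, 30, 15, 4, 12,  5.64, 2.94, 0.87, 0.84,
    2,  8, 15, 30, 5, 12,  5.31, 3.47, 0.88, 0.79,
    2,  9, 34, 25, 3, 12,  2.65, 2.89, 0.93, 0.91,
    2, 10, 25, 34, 3, 16,  2.92, 3.53, 0.83, 0.66,
    2, 11, 27, 21, 4, 16,  4.36, 3.50, 0.58, 0.56,
    2, 12, 21, 27, 3, 14,  3.16, 3.08, 0.72, 0.68
  )
  d %>%
    dplyr::mutate(conc_mean = (.data$conc_blue + .data$conc_yellow) / 2,
                  intensity = relative_intensity(.data$conc_blue, .data$conc_yellow),
                  marked_visits = as.integer(round(1000 * .data$marked_visits_k)),
                  unmarked_visits = as.integer(round(1000 * .data$unmarked_visits_k))) %>%
    dplyr::select("colony", "day", "conc_blue", "conc_yellow", "conc_mean",
                  "intensity", "marked_bees", "unmarked_bees",
                  "marked_visits", "unmarked_visits",
                  "response_marked", "response_unmarked")
}

#' Reconstructed binomial response records from the session table
#'
#' Turns the per-day responses and visit totals of [colony_days()] into
#' fit-ready binomial response records: visit counts become binomial totals,
#' `n_sweeter` is recovered by rounding `response * n_total`, and the two
#' reversal presentations of each concentration pair are pooled with
#' [combine_reversal_pairs()]. Because the source values are printed to two
#' decimals, counts carry rounding error of order 1/200 on the response
#' scale; fits on these records reproduce reported parameter estimates to
#' about that precision.
#'
#' @param group `"unmarked"` (pooled unmarked bees) or `"marked"` (pooled
#'   marked bees).
#' @return A response-record tibble (`colony`, `intensity`, `n_sweeter`,
#'   `n_total`, `response`, `n_days`).
#' @examples
#' colony_response_records("unmarked")
#' @export
colony_response_records <- function(group = c("unmarked", "marked")) {
  group <- match.arg(group)
  d <- colony_days()
  resp <- d[[paste0("response_", group)]]
  visits <- d[[paste0(group, "_visits")]]
  daily <- d %>%
    dplyr::mutate(n_total = visits,
                  n_sweeter = as.integer(round(resp * visits))) %>%
    dplyr::filter(is.finite(resp), .data$n_total > 0)
  combine_reversal_pairs(daily)
}

#' Posterior parameter estimates for the bumblebee datasets
#'
#' Reported posterior means and 95% credible limits of lapse rate, threshold
#' and slope for the three individually tracked bees (B20, B25, B30), the
#' pooled miscellaneous marked bees, the pooled unmarked bees, and the grand
#' pooled dataset. Slopes vary strongly between individuals while thresholds
#' and lapse rates are stable; pooling across individuals lowers the fitted
#' slope (see [run_pooling_experiment()]).
#'
#' @return A tibble with `group`, `n_days`, `term`, `conf.low`, `estimate`,
#'   `conf.high`.
#' @examples
#' est <- psychometric_estimates()
#' ind <- est[est$group %in% c("B20", "B25", "B30") & est$term == "slope", ]
#' mean(ind$estimate)  # individual-mean slope, about 8.2
#' @export
psychometric_estimates <- function() {
  tri <- function(group, n_days, lapse, threshold, slope) {
    tibble::tibble(group = group, n_days = n_days,
                   term = rep(c("lapse", "threshold", "slope"), each = 3),
                   bound = rep(c("conf.low", "estimate", "conf.high"), 3),
                   value = c(lapse, threshold, slope))
  }
  dplyr::bind_rows(
    tri("B20", 7, c(0.19, 0.20, 0.21), c(0.244, 0.247, 0.251), c(10.80, 11.67, 12.59)),
    tri("B25", 9, c(0.33, 0.35, 0.38), c(0.22, 0.23, 0.24),    c(3.19, 4.15, 5.08)),
    tri("B30", 7, c(0.12, 0.13, 0.14), c(0.256, 0.26, 0.263),  c(8.05, 8.82, 9.62)),
    tri("miscellaneous", 24, c(0.17, 0.18, 0.19), c(0.23, 0.24, 0.26), c(2.68, 3.29, 4.35)),
    tri("unmarked", 27, c(0.24, 0.25, 0.26), c(0.21, 0.22, 0.23), c(2.95, 3.12, 3.29)),
    tri("pooled", 27, c(0.22, 0.23, 0.23), c(0.248, 0.251, 0.253), c(4.80, 5.30, 5.80))
  ) %>%
    tidyr::pivot_wider(names_from = "bound", values_from = "value") %>%
    dplyr::select("group", "n_days", "term", "conf.low", "estimate", "conf.high")
}

#' Reference psychometric parameter sets
#'
#' Convenience constructors for two fitted parameter sets used in
#' cross-species comparison: the grand pooled bumblebee curve
#' (threshold 0.251, slope 5.30, lapse 0.23) and the nectar-feeding flower
#' bat *Glossophaga commissarisi* (threshold 0.50, slope 3.41, lapse 0.04)
#' measured in a comparable two-alternative free-choice task. The bumblebee
#' curve has the lower threshold and steeper slope — finer concentration
#' discrimination, consistent with the sweeter nectars of bee-pollinated
#' plants.
#'
#' @param which `"bee_pooled"` or `"bat"`.
#' @return A [psy_params()] object.
#' @examples
#' psy_fun(0.30, reference_params("bee_pooled"))
#' @export
reference_params <- function(which = c("bee_pooled", "bat")) {
  switch(match.arg(which),
         bee_pooled = psy_params(threshold = 0.251, slope = 5.30, lapse = 0.23),
         bat = psy_params(threshold = 0.50, slope = 3.41, lapse = 0.04))
}
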