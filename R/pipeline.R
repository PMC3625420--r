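#' Relative stimulus intensity of a concentration pair
#'
#' The Weber-fraction-like stimulus measure used throughout the package: the
#' absolute difference of the two sucrose concentrations divided by their
#' mean. It increases with the difference between the options (distance
#' effect) and decreases with their common magnitude (magnitude effect), and
#' is symmetric in its arguments with range `[0, 2)`.
#'
#' @param c1,c2 Concentrations (% weight/weight), > 0. Vectorized.
#' @return Relative intensities.
#' @examples
#' relative_intensity(30, 15)  # 0.67
#' relative_intensity(45, 30)  # 0.40
#' @export
relative_intensity <- function(c1, c2) {
  check_positive_vector(c1, "c1")
  check_positive_vector(c2, "c2")
  abs(c1 - c2) / ((c1 + c2) / 2)
}

validate_events <- function(events) {
  if (!is.data.frame(events)) abort("`events` must be a data frame.")
  need <- c("time_s", "bee_id", "feeder_id", "color", "concentration", "rewarded")
  miss <- setdiff(need, names(events))
  if (length(miss)) abort(sprintf("`events` is missing column(s): %s.", paste(miss, collapse = ", ")))
  events <- tibble::as_tibble(events)
  if (!"day" %in% names(events)) events$day <- 1L
  if (!"colony" %in% names(events)) events$colony <- 1L
  bad <- !events$color %in% c("blue", "yellow")
  if (any(bad)) abort("`color` must be \"blue\" or \"yellow\".")
  events
}

validate_conditions <- function(conditions) {
  if (!is.data.frame(conditions)) abort("`conditions` must be a data frame.")
  need <- c("day", "conc_blue", "conc_yellow")
  miss <- setdiff(need, names(conditions))
  if (length(miss)) abort(sprintf("`conditions` is missing column(s): %s.", paste(miss, collapse = ", ")))
  conditions <- tibble::as_tibble(conditions)
  if (!"colony" %in% names(conditions)) conditions$colony <- 1L
  dplyr::mutate(conditions,
    intensity = relative_intensity(.data$conc_blue, .data$conc_yellow),
    sweeter_color = ifelse(.data$conc_blue >= .data$conc_yellow, "blue", "yellow"))
}

join_conditions <- function(events, conditions) {
  events <- validate_events(events)
  conditions <- validate_conditions(conditions)
  out <- dplyr::inner_join(events, conditions, by = c("colony", "day"))
  if (nrow(out) < nrow(events)) {
    warn(sprintf("%d event(s) had no matching (colony, day) condition and were dropped.",
                 nrow(events) - nrow(out)))
  }
  out
}

#' Drop each forager's initial exploration visits
#'
#' Restricts event streams to plateau (asymptotic) performance by removing the
#' first `cutoff` visits of every bee on every day; bees with at most `cutoff`
#' visits on a day contribute nothing for that day. The unmarked-visit stream
#' is treated as one pooled "bee" whose cutoff is usually `cutoff` times the
#' estimated number of unmarked foragers (see [estimate_unmarked_count()]);
#' set it with `unmarked_cutoff`.
#'
#' @param events Event data frame (`time_s`, `bee_id`, `feeder_id`, `color`,
#'   `concentration`, `rewarded`, optional `colony`, `day`).
#' @param cutoff Visits discarded per marked bee per day (default 800, the
#'   point after which daily learning curves are flat).
#' @param unmarked_cutoff Visits discarded from the pooled unmarked stream per
#'   day; defaults to `cutoff`.
#' @param unmarked_id Label identifying unmarked visits (default `"UNMARKED"`).
#' @return The filtered event tibble, ordered by colony, day, time.
#' @export
plateau_filter <- function(events, cutoff = 800, unmarked_cutoff = cutoff,
                           unmarked_id = "UNMARKED") {
  events <- validate_events(events)
  check_number(cutoff, "cutoff", lower = 0)
  check_number(unmarked_cutoff, "unmarked_cutoff", lower = 0)
  events %>%
    dplyr::arrange(.data$colony, .data$day, .data$time_s) %>%
    dplyr::group_by(.data$colony, .data$day, .data$bee_id) %>%
    dplyr::filter(dplyr::row_number() >
                    ifelse(.data$bee_id == unmarked_id, unmarked_cutoff, cutoff)) %>%
    dplyr::ungroup()
}

#' Estimate the number of unmarked foragers
#'
#' Unmarked bees cannot be counted directly; their number is estimated by
#' dividing the total number of unmarked visits by the mean number of daily
#' visits per marked bee. The estimate is returned unrounded; the
#' corresponding plateau cutoff for the pooled unmarked stream is the per-bee
#' cutoff multiplied by this estimate, rounded to the nearest visit.
#'
#' @param total_unmarked_visits Total unmarked visit count (per day, or any
#'   aggregation). Vectorized.
#' @param mean_marked_daily_visits Mean visits per marked bee per day; > 0.
#' @return Fractional bee count(s).
#' @examples
#' estimate_unmarked_count(5000, 1000)              # 5 bees
#' round(800 * estimate_unmarked_count(5000, 1000)) # pooled plateau cutoff
#' @export
estimate_unmarked_count <- function(total_unmarked_visits, mean_marked_daily_visits) {
  if (!is.numeric(mean_marked_daily_visits) || any(!is.finite(mean_marked_daily_visits)) ||
      any(mean_marked_daily_visits <= 0)) {
    abort("`mean_marked_daily_visits` must be > 0.")
  }
  if (any(total_unmarked_visits < 0)) abort("`total_unmarked_visits` must be >= 0.")
  total_unmarked_visits / mean_marked_daily_visits
}

#' Daily discrimination responses from visitation events
#'
#' Reduces (filtered) events to one binomial response per colony-day (or per
#' bee-day): the number of visits to the feeders holding the higher
#' concentration that day over the total number of visits, together with the
#' day's relative intensity. Days without events are simply absent from the
#' output (the undefined-response case); on equal-concentration days the
#' response is computed (blue counted as "sweeter" by convention) but the
#' intensity is 0, and such rows must be excluded before curve fitting.
#'
#' @param events Event data frame.
#' @param conditions Condition data frame (`colony`, `day`, `conc_blue`,
#'   `conc_yellow`).
#' @param by_bee If `TRUE`, one response per bee per day; otherwise visits are
#'   pooled within colony-day.
#' @return A tibble with `colony`, `day`, (`bee_id`,) `conc_blue`,
#'   `conc_yellow`, `intensity`, `n_sweeter`, `n_total`, `response`.
#' @export
daily_response <- function(events, conditions, by_bee = FALSE) {
  ev <- join_conditions(events, conditions)
  keys <- c("colony", "day", if (by_bee) "bee_id",
            "conc_blue", "conc_yellow", "intensity", "sweeter_color")
  ev %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(n_sweeter = sum(.data$color == .data$sweeter_color),
                     n_total = dplyr::n(), .groups = "drop") %>%
    dplyr::mutate(response = .data$n_sweeter / .data$n_total) %>%
    dplyr::select(-"sweeter_color")
}

#' Pool the two reversal presentations of a condition
#'
#' Each concentration pair is presented on two consecutive days with the
#' colors (and positions) exchanged, to cancel color and positional biases.
#' This pools the daily responses of each unordered concentration pair by
#' summing choice counts — equivalent to the visit-weighted mean of the daily
#' responses. A condition observed on a single day passes through unchanged.
#'
#' @param daily Output of [daily_response()] (optionally per bee).
#' @return A tibble with one row per colony (and bee, if present) per
#'   concentration pair: `intensity`, `n_sweeter`, `n_total`, `response`,
#'   `n_days`, suitable as input to [fit_psychometric()].
#' @export
combine_reversal_pairs <- function(daily) {
  need <- c("colony", "conc_blue", "conc_yellow", "intensity", "n_sweeter", "n_total")
  miss <- setdiff(need, names(daily))
  if (length(miss)) abort(sprintf("`daily` is missing column(s): %s.", paste(miss, collapse = ", ")))
  keys <- c("colony", if ("bee_id" %in% names(daily)) "bee_id", "conc_lo", "conc_hi")
  daily %>%
    dplyr::mutate(conc_lo = pmin(.data$conc_blue, .data$conc_yellow),
                  conc_hi = pmax(.data$conc_blue, .data$conc_yellow)) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(intensity = .data$intensity[1],
                     n_sweeter = sum(.data$n_sweeter),
                     n_total = sum(.data$n_total),
                     n_days = dplyr::n(), .groups = "drop") %>%
    dplyr::mutate(response = .data$n_sweeter / .data$n_total) %>%
    dplyr::arrange(.data$colony, .data$intensity)
}

#' Full reduction from raw events to fit-ready response records
#'
#' Convenience wrapper chaining [plateau_filter()], [daily_response()] and
#' [combine_reversal_pairs()]: the standard path from a raw RFID visitation
#' log to the binomial response table consumed by [fit_psychometric()].
#'
#' @inheritParams plateau_filter
#' @inheritParams daily_response
#' @return A response-record tibble (see [combine_reversal_pairs()]).
#' @export
reduce_events <- function(events, conditions, cutoff = 800,
                          unmarked_cutoff = cutoff, by_bee = FALSE) {
  events %>%
    plateau_filter(cutoff = cutoff, unmarked_cutoff = unmarked_cutoff) %>%
    daily_response(conditions, by_bee = by_bee) %>%
    combine_reversal_pairs()
}
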