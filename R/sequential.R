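#' Non-rewarded visit proportions at the two feeder classes
#'
#' Every reward triggers a refill delay during which the feeder is
#' unrewarding, so with many simultaneous foragers a fraction of visits goes
#' unrewarded. This computes, per day, the proportion of non-rewarded visits
#' at the lower-concentration and at the higher-concentration feeder class,
#' and compares the two series with a two-sided paired t test across days
#' (`df = n_days - 1`). Days on which one class received no visits are
#' dropped from the pairing and counted in the output. A zero-variance
#' difference series (e.g. every visit rewarded) yields a flagged result with
#' `NA` statistics rather than an error.
#'
#' @param events Event data frame with `rewarded` flags.
#' @param conditions Condition data frame.
#' @return An object of class `nonreward_analysis`: a list with `proportions`
#'   (per colony-day tibble) and `test` (per colony paired-t tibble).
#'   `tidy()` returns the test table.
#' @export
nonreward_analysis <- function(events, conditions) {
  ev <- join_conditions(events, conditions)
  props <- ev %>%
    dplyr::mutate(class = ifelse(.data$color == .data$sweeter_color, "higher", "lower")) %>%
    dplyr::group_by(.data$colony, .data$day, .data$class) %>%
    dplyr::summarise(prop = mean(!.data$rewarded), n = dplyr::n(), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "class", values_from = c("prop", "n"),
                       values_fill = list(n = 0L))
  for (col in c("prop_lower", "prop_higher", "n_lower", "n_higher")) {
    if (!col %in% names(props)) props[[col]] <- if (grepl("^n_", col)) 0L else NA_real_
  }
  test <- props %>%
    dplyr::group_by(.data$colony) %>%
    dplyr::group_modify(function(d, key) {
      ok <- d$n_lower > 0 & d$n_higher > 0 & is.finite(d$prop_lower) & is.finite(d$prop_higher)
      paired_t_row(d$prop_lower[ok], d$prop_higher[ok], n_dropped = sum(!ok))
    }) %>%
    dplyr::ungroup()
  structure(list(proportions = props, test = test), class = "nonreward_analysis")
}

# Two-sided paired t of x - y; zero-variance or tiny samples are flagged,
# not raised.
paired_t_row <- function(x, y, n_dropped = 0L) {
  n <- length(x)
  base <- tibble::tibble(n_days = n, n_dropped = n_dropped,
                         mean_x = mean(x), mean_y = mean(y),
                         mean_diff = mean(x - y))
  tt <- if (n >= 2) tryCatch(t.test(x, y, paired = TRUE), error = function(e) NULL) else NULL
  if (is.null(tt)) {
    dplyr::mutate(base, statistic = NA_real_, df = n - 1, p_value = NA_real_,
                  zero_variance = n >= 2 && sd(x - y) == 0)
  } else if (!is.finite(tt$statistic)) {
    # a zero-variance, zero-mean difference series gives NaN rather than an error
    dplyr::mutate(base, statistic = NA_real_, df = unname(tt$parameter),
                  p_value = NA_real_, zero_variance = sd(x - y) == 0)
  } else {
    dplyr::mutate(base, statistic = unname(tt$statistic), df = unname(tt$parameter),
                  p_value = tt$p.value, zero_variance = FALSE)
  }
}

#' @export
print.nonreward_analysis <- function(x, ...) {
  cat("<nonreward_analysis> per-day proportions of non-rewarded visits\n")
  print(as.data.frame(x$test), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @rdname nonreward_analysis
#' @param x A `nonreward_analysis` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nonreward_analysis <- function(x, ...) x$test

#' Sequential shift probabilities after reward histories
#'
#' Tests whether foragers downgrade a feeder class after non-rewarded visits
#' (a negative incentive-contrast / lose-shift account). Within each
#' qualifying marked bee's early visit stream, every occurrence of two
#' consecutive visits to the high-concentration color is classified by its
#' reward pattern — RR (two rewards), RN (reward then non-reward), NN (two
#' non-rewards) — and the probability that the *next* visit switches to the
#' low-concentration color is estimated per pattern. Two paired contrasts
#' across bees are then run (two-sided, `df = n_bees - 1`):
#' Prediction 1, shift after NN vs after RN; Prediction 2, shift after NN vs
#' after RR. Under lose-shift both differences should be positive.
#'
#' Only the first `first_n` visits per bee-day on days at the target relative
#' intensity are used (the learning phase, where value updating would show),
#' and bees that never develop a preference above `preference_floor` for the
#' high-concentration color are excluded, as are bees lacking occurrences of
#' a conditioning pattern (from that contrast only).
#'
#' @param events Event data frame.
#' @param conditions Condition data frame.
#' @param target_intensity Relative intensity of the analysis days (default 0.67).
#' @param preference_floor Minimum preference for the high-concentration color
#'   required to include a bee (default 0.90).
#' @param first_n Number of initial visits per bee-day analyzed (default 800).
#' @param intensity_tol Matching tolerance on the intensity (default 0.005,
#'   so conditions quoted to two decimals, e.g. 0.67 for 2/3, still match).
#' @param unmarked_id Label of unmarked visits, which are excluded.
#' @return An object of class `shift_analysis`: list with `per_bee` (per-bee
#'   conditional shift probabilities and occurrence counts), `tests` (the two
#'   paired contrasts) and `excluded` (bees failing the preference floor).
#'   `tidy()` returns the tests.
#' @export
shift_probability_analysis <- function(events, conditions, target_intensity = 0.67,
                                       preference_floor = 0.90, first_n = 800,
                                       intensity_tol = 0.005,
                                       unmarked_id = "UNMARKED") {
  ev <- join_conditions(events, conditions) %>%
    dplyr::filter(abs(.data$intensity - target_intensity) < intensity_tol,
                  .data$bee_id != unmarked_id) %>%
    dplyr::arrange(.data$colony, .data$bee_id, .data$day, .data$time_s) %>%
    dplyr::group_by(.data$colony, .data$bee_id, .data$day) %>%
    dplyr::slice_head(n = first_n) %>%
    dplyr::ungroup()
  if (nrow(ev) == 0L) abort("no marked-bee events at the target intensity.")

  pref <- ev %>%
    dplyr::group_by(.data$colony, .data$bee_id) %>%
    dplyr::summarise(preference = mean(.data$color == .data$sweeter_color),
                     n_visits = dplyr::n(), .groups = "drop")
  keep <- pref %>% dplyr::filter(.data$preference > preference_floor)
  excluded <- pref %>% dplyr::filter(.data$preference <= preference_floor)

  occ <- ev %>%
    dplyr::semi_join(keep, by = c("colony", "bee_id")) %>%
    dplyr::group_by(.data$colony, .data$bee_id, .data$day) %>%
    dplyr::group_modify(function(d, key) pattern_occurrences(
      high = d$color == d$sweeter_color, rewarded = d$rewarded)) %>%
    dplyr::ungroup()

  per_bee <- occ %>%
    dplyr::group_by(.data$colony, .data$bee_id, .data$pattern) %>%
    dplyr::summarise(p_shift = mean(.data$shift), n = dplyr::n(), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "pattern", values_from = c("p_shift", "n"),
                       values_fill = list(n = 0L)) %>%
    dplyr::left_join(keep, by = c("colony", "bee_id"))
  for (col in c("p_shift_RR", "p_shift_RN", "p_shift_NN")) {
    if (!col %in% names(per_bee)) per_bee[[col]] <- NA_real_
  }

  contrast <- function(a, b, label) {
    ok <- is.finite(per_bee[[a]]) & is.finite(per_bee[[b]])
    row <- paired_t_row(per_bee[[a]][ok], per_bee[[b]][ok], n_dropped = sum(!ok))
    dplyr::mutate(row, prediction = label, .before = 1) %>%
      dplyr::rename(n_bees = "n_days", mean_NN = "mean_x", mean_ref = "mean_y")
  }
  tests <- dplyr::bind_rows(
    contrast("p_shift_NN", "p_shift_RN", "Prediction 1 (NN vs RN)"),
    contrast("p_shift_NN", "p_shift_RR", "Prediction 2 (NN vs RR)"))

  structure(list(per_bee = per_bee, tests = tests, excluded = excluded),
            class = "shift_analysis")
}

# Occurrences of two consecutive high-color visits followed by any visit:
# classify the reward pattern and whether the next visit shifts color.
# The reward-then-nonreward order defines RN; the reverse order (NR) is not a
# tested history and is skipped.
pattern_occurrences <- function(high, rewarded) {
  n <- length(high)
  if (n < 3) return(tibble::tibble(pattern = character(), shift = logical()))
  k <- seq_len(n - 2)
  cond <- high[k] & high[k + 1]
  pat <- dplyr::case_when(
    rewarded[k] & rewarded[k + 1] ~ "RR",
    rewarded[k] & !rewarded[k + 1] ~ "RN",
    !rewarded[k] & !rewarded[k + 1] ~ "NN",
    TRUE ~ NA_character_)
  ok <- cond & !is.na(pat)
  tibble::tibble(pattern = pat[ok], shift = !high[k + 2][ok])
}

#' @export
print.shift_analysis <- function(x, ...) {
  cat(sprintf("<shift_analysis> %d qualifying bee(s), %d excluded by preference floor\n",
              nrow(x$per_bee), nrow(x$excluded)))
  print(as.data.frame(x$tests), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @rdname shift_probability_analysis
#' @param x A `shift_analysis` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.shift_analysis <- function(x, ...) x$tests

#' Within-day learning curves
#'
#' Proportion of visits to the higher-concentration feeders over consecutive
#' bins of visits (default 100) within each bee-day, tracking the acquisition
#' of the discrimination. The final partial bin is reported with its size.
#'
#' @param events Event data frame.
#' @param conditions Condition data frame.
#' @param bin Bin width in visits.
#' @return A tibble with `colony`, `bee_id`, `day`, `bin` (1-based index),
#'   `n` (visits in the bin) and `response`.
#' @export
learning_curve <- function(events, conditions, bin = 100) {
  check_number(bin, "bin", lower = 1)
  join_conditions(events, conditions) %>%
    dplyr::arrange(.data$colony, .data$bee_id, .data$day, .data$time_s) %>%
    dplyr::group_by(.data$colony, .data$bee_id, .data$day) %>%
    dplyr::mutate(bin = (dplyr::row_number() - 1L) %/% as.integer(bin) + 1L) %>%
    dplyr::group_by(.data$colony, .data$bee_id, .data$day, .data$bin) %>%
    dplyr::summarise(n = dplyr::n(),
                     response = mean(.data$color == .data$sweeter_color),
                     .groups = "drop")
}
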