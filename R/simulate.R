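#' Configuration for the synthetic colony simulator
#'
#' Describes a simulated colony foraging on a 20-feeder array (two color
#' classes of 10) over a schedule of daily concentration conditions, in the
#' style of an RFID visitation experiment: a mixture of marked
#' (individually identified) and unmarked bees, per-day visit counts drawn
#' from a log-normal matched to a target mean and SD, a refill delay that
#' makes a feeder unrewarding for a fixed time after each reward, and
#' per-bee choice probabilities governed by a true psychometric curve
#' (optionally approached from chance through a learning ramp).
#'
#' @param schedule Data frame of day conditions: `day`, `conc_blue`,
#'   `conc_yellow` (optional `colony`); see [reversal_schedule()].
#' @param n_marked,n_unmarked Numbers of marked and unmarked bees.
#' @param true_params A [psy_params()] object shared by all bees, unless
#'   `per_bee_params` is given.
#' @param per_bee_params Optional tibble (`bee_id`, `threshold`, `slope`,
#'   `lapse`) overriding `true_params` for listed bees.
#' @param visits_mean,visits_sd Target mean and SD of per-bee daily visit
#'   counts (defaults 1076 and 642, typical of marked foragers on such
#'   arrays).
#' @param refill_delay_s Refill delay in seconds (default 10); a feeder is
#'   unrewarding for this long after delivering a reward.
#' @param n_feeders Number of feeders, split evenly between blue and yellow.
#' @param learning_tau Optional visits-constant of an exponential learning
#'   ramp: a bee's probability of choosing the sweeter color on its j-th
#'   visit of the day is `0.5 + (psi - 0.5) * (1 - exp(-j / learning_tau))`.
#'   Around 120 puts the curve within a few percent of asymptote by visit
#'   400-600. `NULL` (default) disables learning (stationary choice).
#' @param session_length_s Foraging session length in seconds (default 12 h).
#' @param unmarked_id Label given to unmarked bees' events.
#' @return An object of class `sim_colony_config`.
#' @export
sim_colony_config <- function(schedule, n_marked = 8, n_unmarked = 25,
                              true_params = psy_params(0.25, 5.3, 0.23),
                              per_bee_params = NULL,
                              visits_mean = 1076, visits_sd = 642,
                              refill_delay_s = 10, n_feeders = 20,
                              learning_tau = NULL, session_length_s = 43200,
                              unmarked_id = "UNMARKED") {
  schedule <- validate_conditions(schedule)
  check_number(n_marked, "n_marked", lower = 0)
  check_number(n_unmarked, "n_unmarked", lower = 0)
  if (n_marked + n_unmarked < 1) abort("at least one bee is required.")
  true_params <- as_psy_params(true_params)
  check_number(visits_mean, "visits_mean", lower = 0, open_lower = TRUE)
  check_number(visits_sd, "visits_sd", lower = 0)
  check_number(refill_delay_s, "refill_delay_s", lower = 0)
  check_number(n_feeders, "n_feeders", lower = 2)
  if (n_feeders %% 2 != 0) abort("`n_feeders` must be even (two equal color classes).")
  if (!is.null(learning_tau)) check_number(learning_tau, "learning_tau", lower = 0, open_lower = TRUE)
  structure(list(schedule = schedule, n_marked = n_marked, n_unmarked = n_unmarked,
                 true_params = true_params, per_bee_params = per_bee_params,
                 visits_mean = visits_mean, visits_sd = visits_sd,
                 refill_delay_s = refill_delay_s, n_feeders = n_feeders,
                 learning_tau = learning_tau, session_length_s = session_length_s,
                 unmarked_id = unmarked_id),
            class = "sim_colony_config")
}

#' Build a reversal-design condition schedule
#'
#' Expands a list of concentration pairs into consecutive-day conditions with
#' the colors exchanged on the second day of each pair — the reversal design
#' that cancels color and positional biases.
#'
#' @param conc_pairs List of length-2 numeric vectors (concentrations, % w/w).
#' @param colony Colony identifier.
#' @return A condition tibble (`colony`, `day`, `conc_blue`, `conc_yellow`).
#' @examples
#' reversal_schedule(list(c(30, 15), c(45, 30)))
#' @export
reversal_schedule <- function(conc_pairs, colony = 1L) {
  rows <- purrr::imap(conc_pairs, function(pr, i) {
    tibble::tibble(colony = colony, day = c(2L * i - 1L, 2L * i),
                   conc_blue = c(pr[1], pr[2]), conc_yellow = c(pr[2], pr[1]))
  })
  dplyr::bind_rows(rows)
}

#' Simulate RFID-style visitation event streams
#'
#' Generates a full event log for the configured colony: per bee and day the
#' visit count is log-normal, visit times are uniform over the session (a
#' Poisson visit process conditioned on its count, i.e. exponential
#' inter-visit gaps), the color class of each visit is Bernoulli with the
#' bee's psychometric probability at that day's relative intensity, and the
#' feeder is uniform within the class. All bees' visits are then merged in
#' time and reward delivery replayed feeder by feeder: a visit is
#' non-rewarded if and only if the feeder delivered a reward within the
#' preceding `refill_delay_s` seconds — so the non-reward rate emerges from
#' forager density, as on the real array.
#'
#' @param config A [sim_colony_config()] object.
#' @param seed Optional integer seed for exact reproducibility.
#' @return An event tibble (`colony`, `day`, `time_s`, `bee_id`,
#'   `feeder_id`, `color`, `concentration`, `rewarded`), time-ordered within
#'   each day, directly consumable by [plateau_filter()], [daily_response()]
#'   and friends.
#' @examples
#' cfg <- sim_colony_config(reversal_schedule(list(c(30, 15))),
#'                          n_marked = 2, n_unmarked = 3, visits_mean = 200,
#'                          visits_sd = 50)
#' ev <- simulate_colony(cfg, seed = 1)
#' @export
simulate_colony <- function(config, seed = NULL) {
  if (!inherits(config, "sim_colony_config")) {
    abort("`config` must be created with sim_colony_config().")
  }
  run <- function() simulate_colony_impl(config)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

simulate_colony_impl <- function(config) {
  bees <- bee_roster(config)
  # log-normal moment-matched to the target mean/SD of daily visit counts
  cv2 <- (config$visits_sd / config$visits_mean)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(config$visits_mean) - sdlog^2 / 2
  half <- config$n_feeders / 2

  days <- purrr::pmap(config$schedule, function(colony, day, conc_blue, conc_yellow,
                                                intensity, sweeter_color, ...) {
    per_bee <- purrr::pmap(bees, function(bee_id, threshold, slope, lapse) {
      n <- max(1L, as.integer(round(rlnorm(1, meanlog, sdlog))))
      psi <- if (intensity > 0) {
        psy_fun(intensity, psy_params(threshold, slope, lapse))
      } else 0.5
      p <- if (is.null(config$learning_tau)) rep(psi, n) else
        0.5 + (psi - 0.5) * (1 - exp(-(seq_len(n)) / config$learning_tau))
      sweet <- runif(n) < p
      color <- ifelse(sweet, sweeter_color, setdiff(c("blue", "yellow"), sweeter_color))
      # blue feeders occupy 1..half on odd days and half+1..n on even days,
      # mimicking the daily positional reversal
      blue_lo <- if (day %% 2 == 1) 0L else half
      feeder <- ifelse(color == "blue",
                       blue_lo + sample.int(half, n, replace = TRUE),
                       (half - blue_lo) + sample.int(half, n, replace = TRUE))
      tibble::tibble(time_s = sort(runif(n, 0, config$session_length_s)),
                     bee_id = bee_id, feeder_id = feeder, color = color)
    })
    ev <- dplyr::arrange(dplyr::bind_rows(per_bee), .data$time_s)
    ev$rewarded <- replay_refills(ev$time_s, ev$feeder_id, config$n_feeders,
                                  config$refill_delay_s)
    ev$colony <- colony
    ev$day <- day
    ev$concentration <- ifelse(ev$color == "blue", conc_blue, conc_yellow)
    ev
  })
  dplyr::bind_rows(days) %>%
    dplyr::select("colony", "day", "time_s", "bee_id", "feeder_id",
                  "color", "concentration", "rewarded")
}

bee_roster <- function(config) {
  ids <- c(if (config$n_marked > 0) sprintf("B%02d", seq_len(config$n_marked)),
           rep(config$unmarked_id, config$n_unmarked))
  roster <- tibble::tibble(bee_id = ids,
                           threshold = config$true_params$threshold,
                           slope = config$true_params$slope,
                           lapse = config$true_params$lapse)
  if (!is.null(config$per_bee_params)) {
    ov <- tibble::as_tibble(config$per_bee_params)
    idx <- match(roster$bee_id, ov$bee_id)
    hit <- !is.na(idx)
    for (col in c("threshold", "slope", "lapse")) {
      if (col %in% names(ov)) roster[[col]][hit] <- ov[[col]][idx[hit]]
    }
  }
  roster
}

# Sequential replay of reward delivery: a feeder delivers only if its last
# delivery is at least `delay` seconds in the past.
replay_refills <- function(time_s, feeder_id, n_feeders, delay) {
  last <- rep(-Inf, n_feeders)
  rewarded <- logical(length(time_s))
  for (i in seq_along(time_s)) {
    f <- feeder_id[i]
    if (time_s[i] - last[f] >= delay) {
      rewarded[i] <- TRUE
      last[f] <- time_s[i]
    }
  }
  rewarded
}

#' Simulate binomial response records from a true curve
#'
#' Direct fixture generator for fitting: at each intensity the number of
#' visits to the sweeter option is binomial with probability given by the
#' true psychometric curve.
#'
#' @param true_params A [psy_params()] object.
#' @param intensities Relative intensities (> 0).
#' @param n_per Visits per intensity.
#' @param seed Optional integer seed.
#' @return A response-record tibble (`intensity`, `n_sweeter`, `n_total`).
#' @examples
#' simulate_binomial_responses(psy_params(0.25, 5, 0.15),
#'                             c(0.05, 0.25, 0.6), n_per = 200, seed = 1)
#' @export
simulate_binomial_responses <- function(true_params, intensities, n_per, seed = NULL) {
  true_params <- as_psy_params(true_params)
  check_positive_vector(intensities, "intensities")
  check_number(n_per, "n_per", lower = 1)
  run <- function() {
    tibble::tibble(intensity = intensities,
                   n_sweeter = rbinom(length(intensities), n_per,
                                      psy_fun(intensities, true_params)),
                   n_total = as.integer(n_per))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
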