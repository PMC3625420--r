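# Shared fixture builders. All synthetic data is generated in code at test
# time under fixed seeds.

# Independent reference implementation of the psychometric curve via the
# Weibull distribution function: the inner double exponential of the printed
# formula equals the CDF of a Weibull with shape k = 2sm/ln2 and scale
# m * ln(2)^(-1/k), so Psi = 0.5*lapse + (1-lapse)*(0.5 + 0.5*F(x)).
psy_oracle <- function(x, threshold, slope, lapse) {
  k <- 2 * slope * threshold / log(2)
  f <- stats::pweibull(x, shape = k, scale = threshold * log(2)^(-1 / k))
  0.5 * lapse + (1 - lapse) * (0.5 + 0.5 * f)
}

# Sample x values whose curve response stays strictly inside the open
# asymptote interval in double precision (steep curves saturate quickly).
psy_safe_x <- function(p, n, u_lo = 1e-5, u_hi = 1 - 1e-9) {
  k <- 2 * p$slope * p$threshold / log(2)
  scale <- p$threshold * log(2)^(-1 / k)
  u <- sort(runif(n, u_lo, u_hi))
  scale * (-log1p(-u))^(1 / k)
}

random_params <- function() {
  psy_params(threshold = runif(1, 0.05, 2),
             slope = runif(1, 0.5, 12),
             lapse = runif(1, 0, 0.5))
}

# Minimal single-condition schedule: blue sweeter on day 1.
one_day_conditions <- function(conc_blue = 30, conc_yellow = 15, colony = 1L) {
  tibble::tibble(colony = colony, day = 1L,
                 conc_blue = conc_blue, conc_yellow = conc_yellow)
}

# Hand-built event stream with fully controlled colors and reward flags.
make_events <- function(colors, rewarded = TRUE, bee_id = "B01", day = 1L,
                        colony = 1L, conc_blue = 30, conc_yellow = 15) {
  n <- length(colors)
  tibble::tibble(colony = colony, day = day, time_s = seq_len(n) * 5,
                 bee_id = bee_id,
                 feeder_id = ifelse(colors == "blue", 1L, 11L),
                 color = colors,
                 concentration = ifelse(colors == "blue", conc_blue, conc_yellow),
                 rewarded = rep_len(rewarded, n))
}

# Sequential choice generator with history-dependent shift probability:
# while on the high (sweeter) color, the chance of switching away on the next
# visit depends on the reward pattern of the last two high-color visits.
# Rewards are iid Bernoulli(reward_p). Off the high color the bee returns
# with probability `return_p`.
make_history_bee <- function(n, q_rr, q_rn, q_nn, q_nr = q_rn,
                             reward_p = 0.5, return_p = 0.95,
                             bee_id = "B01", day = 1L) {
  high <- logical(n); rew <- logical(n)
  high[1:2] <- TRUE
  rew[1:2] <- runif(2) < reward_p
  for (i in 3:n) {
    if (high[i - 2] && high[i - 1]) {
      q <- if (rew[i - 2] && rew[i - 1]) q_rr
      else if (rew[i - 2] && !rew[i - 1]) q_rn
      else if (!rew[i - 2] && !rew[i - 1]) q_nn
      else q_nr
      high[i] <- runif(1) >= q
    } else if (!high[i - 1]) {
      high[i] <- runif(1) < return_p
    } else {
      high[i] <- TRUE
    }
    rew[i] <- runif(1) < reward_p
  }
  make_events(ifelse(high, "blue", "yellow"), rewarded = rew,
              bee_id = bee_id, day = day)
}

expect_tidy_summary <- function(summ) {
  expect_true(all(c("term", "estimate", "conf.low", "conf.high") %in% names(summ)))
  expect_setequal(summ$term, c("threshold", "slope", "lapse"))
  expect_true(all(summ$conf.low <= summ$estimate & summ$estimate <= summ$conf.high))
}
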