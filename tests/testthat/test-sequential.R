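test_that("non-reward proportions are computed per feeder class and day", {
  # day 1: sweeter (blue) class 2/10 non-rewarded, lower (yellow) 5/10
  ev1 <- make_events(c(rep("blue", 10), rep("yellow", 10)),
                     rewarded = c(rep(TRUE, 8), rep(FALSE, 2),
                                  rep(TRUE, 5), rep(FALSE, 5)))
  ev2 <- dplyr::mutate(make_events(c(rep("blue", 10), rep("yellow", 10)),
                                   rewarded = c(rep(TRUE, 9), FALSE,
                                                rep(TRUE, 8), rep(FALSE, 2))),
                       day = 2L)
  cond <- dplyr::bind_rows(one_day_conditions(),
                           dplyr::mutate(one_day_conditions(), day = 2L))
  res <- nonreward_analysis(dplyr::bind_rows(ev1, ev2), cond)
  pr <- dplyr::arrange(res$proportions, .data$day)
  expect_equal(pr$prop_higher, c(0.2, 0.1))
  expect_equal(pr$prop_lower, c(0.5, 0.2))
  tt <- tidy(res)
  expect_equal(tt$n_days, 2)
  expect_equal(tt$df, 1)
  expect_equal(tt$mean_diff, mean(c(0.5 - 0.2, 0.2 - 0.1)))
})

test_that("all-rewarded streams give a flagged zero-variance test, not an error", {
  ev <- dplyr::bind_rows(
    make_events(c(rep("blue", 10), rep("yellow", 5)), rewarded = TRUE),
    dplyr::mutate(make_events(c(rep("blue", 10), rep("yellow", 5)),
                              rewarded = TRUE), day = 2L))
  cond <- dplyr::bind_rows(one_day_conditions(),
                           dplyr::mutate(one_day_conditions(), day = 2L))
  res <- nonreward_analysis(ev, cond)
  tt <- tidy(res)
  expect_true(tt$zero_variance)
  expect_true(is.na(tt$statistic))
  expect_true(is.na(tt$p_value))
  expect_equal(tt$mean_diff, 0)
})

test_that("history-dependent lose-shift bees yield positive NN contrasts", {
  withr::with_seed(51, {
    ev <- dplyr::bind_rows(lapply(1:10, function(i) {
      make_history_bee(800, q_rr = 0.02, q_rn = 0.05, q_nn = 0.15,
                       bee_id = sprintf("B%02d", i))
    }))
    res <- shift_probability_analysis(ev, one_day_conditions())
    tt <- tidy(res)
    expect_equal(nrow(tt), 2)
    expect_true(all(tt$mean_diff > 0))      # NN raises the shift probability
    expect_true(all(tt$p_value < 0.05))
    expect_equal(tt$df, tt$n_bees - 1)
    # per-bee conditionals are ordered the way they were generated
    expect_true(mean(res$per_bee$p_shift_NN) > mean(res$per_bee$p_shift_RR))
  })
})

test_that("memoryless bees show no NN contrast on average", {
  withr::with_seed(52, {
    ev <- dplyr::bind_rows(lapply(1:12, function(i) {
      make_history_bee(800, q_rr = 0.06, q_rn = 0.06, q_nn = 0.06,
                       bee_id = sprintf("B%02d", i))
    }))
    tt <- tidy(shift_probability_analysis(ev, one_day_conditions()))
    expect_true(all(abs(tt$mean_diff) < 0.05))
    expect_true(all(tt$p_value > 0.01))
  })
})

test_that("shift analysis applies the preference floor and intensity filter", {
  withr::with_seed(53, {
    good <- make_history_bee(600, q_rr = 0.02, q_rn = 0.02, q_nn = 0.02,
                             bee_id = "B01")
    # a bee that mostly sits on the lower concentration never qualifies
    bad <- make_events(sample(c("blue", "yellow"), 600, TRUE, c(0.4, 0.6)),
                       rewarded = runif(600) < 0.5, bee_id = "B02")
    res <- shift_probability_analysis(dplyr::bind_rows(good, bad),
                                      one_day_conditions())
    expect_equal(res$excluded$bee_id, "B02")
    expect_equal(unique(res$per_bee$bee_id), "B01")
  })
  # days at other intensities are ignored entirely
  off <- make_events(rep("blue", 100), conc_blue = 45, conc_yellow = 30)
  expect_error(shift_probability_analysis(off, one_day_conditions(45, 30)),
               "target intensity")
})

test_that("unmarked visits never enter the shift analysis", {
  withr::with_seed(54, {
    ev <- dplyr::bind_rows(
      make_history_bee(600, 0.02, 0.05, 0.15, bee_id = "B01"),
      make_history_bee(600, 0.02, 0.05, 0.15, bee_id = "UNMARKED"))
    res <- shift_probability_analysis(ev, one_day_conditions())
    expect_false("UNMARKED" %in% res$per_bee$bee_id)
    expect_false("UNMARKED" %in% res$excluded$bee_id)
  })
})

test_that("learning curves bin visits in order and track acquisition", {
  ev <- make_events(c(rep("yellow", 100), rep("blue", 150)))
  lc <- learning_curve(ev, one_day_conditions(), bin = 100)
  expect_equal(lc$bin, 1:3)
  expect_equal(lc$n, c(100L, 100L, 50L))
  expect_equal(lc$response, c(0, 1, 1))
  # a simulated learner rises from near chance toward its asymptote
  cfg <- sim_colony_config(one_day_conditions(), n_marked = 1, n_unmarked = 0,
                           visits_mean = 1200, visits_sd = 1,
                           learning_tau = 60)
  lcs <- learning_curve(simulate_colony(cfg, seed = 55), cfg$schedule)
  expect_lt(lcs$response[1], lcs$response[nrow(lcs)] - 0.05)
  expect_lt(lcs$response[1], 0.7)
})
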