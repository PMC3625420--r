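test_that("zero refill delay rewards every visit; a positive delay does not", {
  cfg0 <- sim_colony_config(one_day_conditions(), n_marked = 2, n_unmarked = 8,
                            visits_mean = 300, visits_sd = 50,
                            refill_delay_s = 0)
  expect_true(all(simulate_colony(cfg0, seed = 61)$rewarded))
  cfg1 <- sim_colony_config(one_day_conditions(), n_marked = 2, n_unmarked = 8,
                            visits_mean = 300, visits_sd = 50,
                            refill_delay_s = 60)
  expect_gt(mean(!simulate_colony(cfg1, seed = 61)$rewarded), 0)
})

test_that("choice frequencies match the true curve at the day's intensity", {
  cfg <- sim_colony_config(one_day_conditions(), n_marked = 1, n_unmarked = 0,
                           visits_mean = 20000, visits_sd = 1)
  ev <- simulate_colony(cfg, seed = 62)
  psi <- psy_fun(relative_intensity(30, 15), cfg$true_params)
  expect_equal(mean(ev$color == "blue"), psi, tolerance = 0.015)
})

test_that("simulation is reproducible under a seed and varies across seeds", {
  cfg <- sim_colony_config(reversal_schedule(list(c(30, 15))), n_marked = 2,
                           n_unmarked = 2, visits_mean = 200, visits_sd = 50)
  expect_identical(simulate_colony(cfg, seed = 63), simulate_colony(cfg, seed = 63))
  expect_false(identical(simulate_colony(cfg, seed = 63),
                         simulate_colony(cfg, seed = 64)))
})

test_that("binomial fixture generator obeys the law of large numbers", {
  p <- psy_params(0.25, 5, 0.15)
  xs <- c(0.05, 0.25, 0.6)
  recs <- simulate_binomial_responses(p, xs, n_per = 2e5, seed = 65)
  expect_equal(recs$n_sweeter / recs$n_total, psy_fun(xs, p), tolerance = 0.004)
  expect_identical(recs$n_total, rep(200000L, 3))
})

test_that("reversal schedules exchange colors on consecutive days", {
  sch <- reversal_schedule(list(c(30, 15), c(45, 30)))
  expect_equal(sch$day, 1:4)
  expect_equal(sch$conc_blue, c(30, 15, 45, 30))
  expect_equal(sch$conc_yellow, c(15, 30, 30, 45))
})

test_that("per-bee parameter overrides change only the listed bee", {
  ov <- tibble::tibble(bee_id = "B01", threshold = 0.6, slope = 2, lapse = 0.4)
  cfg <- sim_colony_config(one_day_conditions(), n_marked = 2, n_unmarked = 0,
                           per_bee_params = ov, visits_mean = 8000,
                           visits_sd = 1)
  ev <- simulate_colony(cfg, seed = 66)
  x <- relative_intensity(30, 15)
  p1 <- mean(ev$color[ev$bee_id == "B01"] == "blue")
  p2 <- mean(ev$color[ev$bee_id == "B02"] == "blue")
  expect_equal(p1, psy_fun(x, psy_params(0.6, 2, 0.4)), tolerance = 0.02)
  expect_equal(p2, psy_fun(x, cfg$true_params), tolerance = 0.02)
})

test_that("non-reward rate rises with forager density", {
  mk <- function(n_unmarked) {
    cfg <- sim_colony_config(one_day_conditions(), n_marked = 2,
                             n_unmarked = n_unmarked,
                             visits_mean = 400, visits_sd = 50)
    mean(!simulate_colony(cfg, seed = 67)$rewarded)
  }
  expect_gt(mk(30), mk(2))
})

test_that("stationary choice makes the plateau filter response-neutral", {
  cfg <- sim_colony_config(one_day_conditions(), n_marked = 1, n_unmarked = 0,
                           visits_mean = 4000, visits_sd = 1)
  ev <- simulate_colony(cfg, seed = 68)
  early <- mean(ev$color[1:2000] == "blue")
  late <- mean(ev$color[-(1:2000)] == "blue")
  expect_equal(early, late, tolerance = 0.05)
})

test_that("generator to pipeline to fit recovers the generating curve", {
  sch <- reversal_schedule(list(c(30, 15), c(45, 30), c(25, 20), c(50, 45)))
  cfg <- sim_colony_config(sch, n_marked = 0, n_unmarked = 10,
                           visits_mean = 500, visits_sd = 150)
  ev <- simulate_colony(cfg, seed = 69)
  recs <- combine_reversal_pairs(daily_response(ev, sch))
  fit <- fit_psychometric(recs, n_draws = 1500, seed = 69)
  s <- tidy(fit)
  truth <- c(threshold = cfg$true_params$threshold,
             slope = cfg$true_params$slope, lapse = cfg$true_params$lapse)
  inside <- s$conf.low <= truth[s$term] & truth[s$term] <= s$conf.high
  expect_true(all(inside), info = paste(s$term[!inside], collapse = ", "))
})
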