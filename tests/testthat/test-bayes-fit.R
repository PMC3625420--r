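test_that("log-posterior composes binomial likelihood and priors", {
  rec <- tibble::tibble(intensity = 1, n_sweeter = 0, n_total = 1)
  pars <- list(threshold = 1, slope = 2, lapse = 0.2)  # Psi(1) = 0.70
  none <- rec[0, ]
  # subtracting the prior-only density isolates the single-trial likelihood
  expect_equal(log_posterior(pars, rec) - log_posterior(pars, none), log(0.30))
  expect_identical(log_posterior(list(threshold = 1, slope = 2, lapse = 1), rec), -Inf)
  expect_identical(log_posterior(list(threshold = -1, slope = 2, lapse = 0.1), rec), -Inf)
})

test_that("log-posterior differences match independent term-by-term sums", {
  recs <- tibble::tibble(intensity = c(0.1, 0.3, 0.6),
                         n_sweeter = c(21, 35, 44), n_total = c(40, 50, 50))
  oracle_lp <- function(th, sl, la) {
    psi <- psy_oracle(recs$intensity, th, sl, la)
    sum(recs$n_sweeter * log(psi) + (recs$n_total - recs$n_sweeter) * log(1 - psi)) +
      dnorm(th, 1, 0.5, log = TRUE) + dnorm(sl, 2, 1, log = TRUE) +
      dbeta(la, 2, 20, log = TRUE)
  }
  p1 <- list(threshold = 0.3, slope = 4, lapse = 0.1)
  p2 <- list(threshold = 0.8, slope = 1.5, lapse = 0.3)
  expect_equal(log_posterior(p1, recs) - log_posterior(p2, recs),
               oracle_lp(0.3, 4, 0.1) - oracle_lp(0.8, 1.5, 0.3),
               tolerance = 1e-10)
})

test_that("sampler is bit-reproducible under a seed", {
  recs <- simulate_binomial_responses(psy_params(0.25, 5, 0.15),
                                      c(0.05, 0.2, 0.4, 0.6), 100, seed = 5)
  f1 <- fit_psychometric(recs, n_draws = 300, seed = 42)
  f2 <- fit_psychometric(recs, n_draws = 300, seed = 42)
  expect_identical(f1$draws, f2$draws)
  expect_tidy_summary(tidy(f1))
})

test_that("posterior means agree with the grid-integration oracle on small data", {
  withr::with_seed(21, {
    for (rep in 1:3) {
      truth <- psy_params(runif(1, 0.15, 0.6), runif(1, 2, 6), runif(1, 0.02, 0.25))
      recs <- simulate_binomial_responses(truth, c(0.08, 0.2, 0.35, 0.6), 50)
      fit <- fit_psychometric(recs, n_draws = 2500)
      grd <- grid_posterior(recs, resolution = 121)
      mcse <- fit$summary$std.error / sqrt(fit$summary$ess)
      gap <- abs(fit$summary$estimate - grd$summary$estimate)
      expect_true(all(gap <= 3 * mcse + 1e-3),
                  info = paste("gap:", paste(signif(gap, 3), collapse = " ")))
    }
  })
})

test_that("flat slope prior variant also matches the grid oracle", {
  recs <- simulate_binomial_responses(psy_params(0.3, 4, 0.1),
                                      c(0.1, 0.25, 0.5), 60, seed = 8)
  pri <- flat_slope_priors(slope_max = 15)
  fit <- fit_psychometric(recs, priors = pri, n_draws = 2500, seed = 8)
  grd <- grid_posterior(recs, priors = pri, resolution = 121)
  mcse <- fit$summary$std.error / sqrt(fit$summary$ess)
  expect_true(all(abs(fit$summary$estimate - grd$summary$estimate) <= 3 * mcse + 1e-3))
})

test_that("prior-only posterior recovers the prior means", {
  none <- tibble::tibble(intensity = numeric(), n_sweeter = integer(),
                         n_total = integer())
  fit <- fit_psychometric(none, n_draws = 4000, seed = 9)
  # truncated-normal means: mu + sd * phi(-mu/sd) / Phi(mu/sd)
  tn_mean <- function(mu, sd) mu + sd * dnorm(-mu / sd) / pnorm(mu / sd)
  est <- setNames(fit$summary$estimate, fit$summary$term)
  mcse <- setNames(fit$summary$std.error / sqrt(fit$summary$ess), fit$summary$term)
  expect_equal(unname(est["threshold"]), tn_mean(1, 0.5), tolerance = 4 * mcse["threshold"] + 0.01)
  expect_equal(unname(est["slope"]), tn_mean(2, 1), tolerance = 4 * mcse["slope"] + 0.02)
  expect_equal(unname(est["lapse"]), 2 / 22, tolerance = 4 * mcse["lapse"] + 0.005)
  expect_true(fit$diagnostics$prior_dominated)
})

test_that("parameter recovery puts generating values inside the credible intervals", {
  truth <- psy_params(0.25, 5, 0.15)
  xs <- c(0.05, 0.15, 0.25, 0.3, 0.4, 0.5, 0.6)
  withr::with_seed(23, {
    for (rep in 1:3) {
      recs <- simulate_binomial_responses(truth, xs, 2000)
      fit <- fit_psychometric(recs, n_draws = 2000)
      s <- tidy(fit)
      truth_v <- c(threshold = 0.25, slope = 5, lapse = 0.15)
      inside <- s$conf.low <= truth_v[s$term] & truth_v[s$term] <= s$conf.high
      expect_true(all(inside), info = paste(s$term[!inside], collapse = ", "))
    }
  })
})

test_that("uninformative flat responses leave the threshold posterior near its prior", {
  recs <- tibble::tibble(intensity = c(0.1, 0.3, 0.6),
                         n_sweeter = c(50, 50, 50), n_total = 100)
  fit <- fit_psychometric(recs, n_draws = 2000, seed = 3)
  thr <- tidy(fit)[tidy(fit)$term == "threshold", ]
  expect_gt(thr$estimate, 0.7)           # near the prior mean of ~1
  expect_gt(thr$conf.high - thr$conf.low, 0.8)  # wide, prior-scale interval
  expect_true(fit$diagnostics$prior_dominated)
})

test_that("degenerate designs warn but fit", {
  recs <- tibble::tibble(intensity = 0.3, n_sweeter = 80, n_total = 100)
  expect_warning(fit_psychometric(recs, n_draws = 200, seed = 2), "distinct")
})

test_that("grid oracle flags an under-resolved grid and degenerate prior peaks", {
  sharp <- prior_spec(threshold_sd = 0.01, slope_sd = 0.01, lapse_shape1 = 200,
                      lapse_shape2 = 2000)
  g <- grid_posterior(tibble::tibble(intensity = 0.3, n_sweeter = 3, n_total = 5),
                      priors = sharp, resolution = 201,
                      bounds = list(threshold = c(0.9, 1.1), slope = c(1.9, 2.1),
                                    lapse = c(0.05, 0.15)))
  est <- setNames(g$summary$estimate, g$summary$term)
  expect_equal(unname(est["threshold"]), 1, tolerance = 0.01)
  expect_equal(unname(est["slope"]), 2, tolerance = 0.01)
  # heavy counts against a coarse default grid: refinement must move the mass
  big <- tibble::tibble(intensity = c(0.1, 0.3, 0.6),
                        n_sweeter = c(2500, 4000, 4400), n_total = 5000)
  expect_error(grid_posterior(big, resolution = 11, verify_resolution = TRUE),
               "resolution")
})
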