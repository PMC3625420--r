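test_that("curve matches an independent Weibull-CDF implementation", {
  # hand-verified high-precision value at the pooled bumblebee parameters
  expect_equal(psy_fun(0.30, psy_params(0.251, 5.30, 0.23)),
               0.787595124023716, tolerance = 1e-12)
  withr::with_seed(11, {
    for (i in 1:25) {
      p <- random_params()
      x <- exp(runif(5, log(0.01), log(5)))
      expect_equal(psy_fun(x, p),
                   psy_oracle(x, p$threshold, p$slope, p$lapse),
                   tolerance = 1e-10)
    }
  })
})

test_that("threshold and asymptote identities hold for arbitrary parameters", {
  expect_identical(psy_fun(0.25, psy_params(0.25, 5, 0)), 0.75)
  expect_equal(psy_fun(1e-9, psy_params(0.25, 5, 0.1)), 0.5, tolerance = 1e-6)
  expect_equal(psy_fun(1e9, psy_params(0.25, 5, 0.23)), 0.885, tolerance = 1e-9)
  withr::with_seed(12, {
    for (i in 1:25) {
      p <- random_params()
      expect_equal(psy_fun(p$threshold, p), 0.75 - 0.25 * p$lapse, tolerance = 1e-12)
      x <- psy_safe_x(p, 20)
      v <- psy_fun(x, p)
      expect_true(all(v > 0.5 & v < 1 - p$lapse / 2))
      # strict monotonicity on ordered points inside the unsaturated region
      expect_true(all(diff(v) > 0))
    }
  })
})

test_that("slope parameter is the threshold slope of the unscaled discrimination curve", {
  # the 2-AFC rescaling Psi = (1 + F)/2 halves the visible slope, so the
  # derivative of 2*Psi - 1 at the threshold recovers s exactly
  withr::with_seed(13, {
    for (i in 1:10) {
      p <- random_params()
      m <- p$threshold
      h <- 1e-6 * m
      fd <- (psy_fun(m + h, psy_params(m, p$slope, 0)) -
               psy_fun(m - h, psy_params(m, p$slope, 0))) / (2 * h)
      expect_equal(2 * fd, p$slope, tolerance = 1e-4)
    }
  })
})

test_that("inverse round-trips through the curve and hits the threshold at 0.75", {
  expect_equal(psy_inverse(0.75, psy_params(0.25, 5, 0)), 0.25, tolerance = 1e-9)
  expect_equal(psy_inverse(0.6925, psy_params(0.25, 5, 0.23)), 0.25, tolerance = 1e-7)
  expect_equal(psy_inverse(0.787595124023716, psy_params(0.251, 5.30, 0.23)),
               0.30, tolerance = 1e-6)
  withr::with_seed(14, {
    for (i in 1:15) {
      p <- random_params()
      x <- psy_safe_x(p, 4, u_lo = 1e-4, u_hi = 1 - 1e-6)
      expect_equal(psy_inverse(psy_fun(x, p), p), x, tolerance = 1e-6)
    }
  })
})

test_that("domain violations raise errors naming the offending quantity", {
  expect_error(psy_fun(-1, psy_params(0.25, 5, 0)), "x")
  expect_error(psy_fun(0, psy_params(0.25, 5, 0)), "x")
  expect_error(psy_params(-0.1, 5, 0), "threshold")
  expect_error(psy_params(0.25, 0, 0), "slope")
  expect_error(psy_params(0.25, 5, 1), "lapse")
  expect_error(psy_inverse(0.5, psy_params(0.25, 5, 0)), "between")
  expect_error(psy_inverse(0.9, psy_params(0.25, 5, 0.23)), "between")
})

test_that("lapse rate inverts the upper asymptote", {
  expect_identical(lapse_from_upper_asymptote(1), 0)
  expect_equal(lapse_from_upper_asymptote(0.885), 0.23)
  expect_equal(lapse_from_upper_asymptote(0.98), 0.04)
  expect_error(lapse_from_upper_asymptote(0.5), "0.5")
  expect_error(lapse_from_upper_asymptote(1.01), "0.5")
})
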