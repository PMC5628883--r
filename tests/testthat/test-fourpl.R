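test_that("forward curve and analytic inversion are mutually consistent", {
  set.seed(11)
  for (i in 1:20) {
    cv <- dose_response_curve(top = runif(1, 60, 100), bottom = runif(1, 0, 10),
                              ec50 = 10^runif(1, 0, 3), hill = runif(1, 0.4, 4))
    d <- 10^runif(5, -1, 3.5)
    e <- predict(cv, d)
    back <- invert_curve(effect_as_fraction(cv), e / 100)
    expect_equal(back, d, tolerance = 1e-7)
  }
  cv <- dose_response_curve(100, 0, 10, 1)
  expect_equal(predict(cv, 0), 0)
  expect_equal(predict(cv, Inf), 100)
})

test_that("constructor rejects invalid curve parameters", {
  expect_error(dose_response_curve(50, 60, 10, 1), "bottom")
  expect_error(dose_response_curve(100, 0, -1, 1), "ec50")
  expect_error(dose_response_curve(100, 0, 10, 0), "hill")
})

test_that("noiseless 4PL data are recovered essentially exactly", {
  doses <- screening_doses()
  eff <- fourpl(doses, top = 100, bottom = 0, ec50 = 500, hill = 1)
  fit <- fit_4pl(doses, eff)
  expect_equal(fit$top, 100, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-4)
  expect_equal(fit$ec50, 500, tolerance = 1e-5)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_true(fit$diagnostics$converged)
})

test_that("a gross outlier is down-weighted and barely shifts the EC50", {
  doses <- screening_doses()
  clean <- fourpl(doses, 100, 0, 500, 1)
  dirty <- clean
  dirty[4] <- dirty[4] + 50
  fit_clean <- fit_4pl(doses, clean)
  fit_robust <- fit_4pl(doses, dirty)
  fit_naive <- fit_4pl(doses, dirty, robust = FALSE)
  shift_robust <- abs(log10(fit_robust$ec50) - log10(fit_clean$ec50))
  shift_naive <- abs(log10(fit_naive$ec50) - log10(fit_clean$ec50))
  expect_lt(shift_robust, 0.05)
  expect_gt(shift_naive, shift_robust)
  expect_true(any(fit_robust$diagnostics$outlier))
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(fit_4pl(c(1, 10, 100), c(0, 50, 100)), "at least 5")
  expect_error(fit_4pl(c(1, 2, 3, 4, 5), c(0, 10, 30, 60, 90)), "two log10")
  expect_error(fit_4pl(10^(0:5), rep(50, 6)), "flat")
})

test_that("screening mode constrains the infinite-dose asymptote", {
  doses <- screening_doses()
  eff <- fourpl(doses, top = 30, bottom = 0, ec50 = 500, hill = 1)
  fit <- fit_4pl(doses, eff, lower_asymptote_bounds = c(50, 100))
  expect_gte(fit$top, 50)
  expect_lte(fit$top, 100)
})

test_that("GI50 inverts the fitted curve and censors unreachable levels", {
  expect_equal(gi50(dose_response_curve(100, 0, 10, 1))$dose, 10)
  # asymmetric slope, analytic inverse
  expect_equal(gi50(dose_response_curve(100, 0, 10, 2))$dose, 10)
  g <- gi50(dose_response_curve(100, 20, 7, 1.5), level = 60)
  expect_equal(predict(dose_response_curve(100, 20, 7, 1.5), g$dose), 60)
  # maximal effect below the level: censored above the tested range
  g_hi <- gi50(dose_response_curve(40, 0, 10, 1), max_dose = 1000)
  expect_true(g_hi$censored)
  expect_identical(g_hi$dose, Inf)
  expect_match(g_hi$label, ">")
  # zero-dose effect already above the level: censored below
  g_lo <- gi50(dose_response_curve(100, 60, 10, 1))
  expect_true(g_lo$censored)
  expect_equal(g_lo$dose, 0)
})

test_that("inverse consistency: fitting then GI50 returns the generating EC50", {
  doses <- c(0, screening_doses())
  eff <- fourpl(doses, 100, 0, 200, 1.3)
  fit <- fit_4pl(doses, eff)
  expect_equal(gi50(fit)$dose, 200, tolerance = 1e-4)
})

test_that("percent/fraction converters are exact inverses", {
  cv <- dose_response_curve(90, 5, 12, 1.7)
  back <- effect_as_percent(effect_as_fraction(cv))
  expect_equal(back[c("top", "bottom", "ec50", "hill")],
               cv[c("top", "bottom", "ec50", "hill")])
  expect_equal(effect_as_fraction(55), 0.55)
})
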