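test_that("Bliss independence expectation is the probabilistic union", {
  expect_equal(bliss_expected(0.5, 0.5), 0.75)
  expect_equal(bliss_expected(0, 0.37), 0.37)
  expect_equal(bliss_expected(1, 0.2), 1)
  expect_equal(bliss_expected(c(0.1, 0.9), 0.5), c(0.55, 0.95))
  expect_error(bliss_expected(1.2, 0.5), "fractions")
})

test_that("curve inversion returns sentinels at the asymptotes", {
  cv <- dose_response_curve(1, 0, 10, 1)
  expect_equal(invert_curve(cv, 0.75), 30)
  d <- invert_curve(cv, 1)
  expect_true(is.infinite(as.numeric(d)))
  expect_true(isTRUE(attr(d, "saturated")))
  expect_equal(invert_curve(cv, 0), 0)
})

test_that("zero doses reduce the Loewe expectation to single-agent effects", {
  ca <- dose_response_curve(1, 0, 10, 1.5)
  cb <- dose_response_curve(0.9, 0, 40, 0.8)
  expect_equal(loewe_expected(ca, cb, 25, 0), predict(ca, 25))
  expect_equal(loewe_expected(ca, cb, 0, 25), predict(cb, 25))
  expect_equal(loewe_expected(ca, cb, 0, 0), 0)
})

test_that("sham self-combination is exactly Loewe-additive for any curve", {
  set.seed(42)
  doses <- default_dose_grid()
  for (i in 1:15) {
    cv <- random_curve()
    for (da in doses[c(1, 4, 7, 9)]) for (db in doses[c(2, 5, 8)]) {
      e <- loewe_expected(cv, cv, da, db)
      expect_equal(as.numeric(e), predict(cv, da + db), tolerance = 1e-6)
    }
  }
})

test_that("hill-1 identical curves obey the closed-form Loewe solution", {
  cv <- dose_response_curve(1, 0, 10, 1)
  for (d in c(1, 5, 10, 50)) {
    analytic <- predict(cv, 2 * d)  # dose-equivalence of equal hill-1 curves
    expect_equal(loewe_expected(cv, cv, d, d), analytic, tolerance = 1e-8)
    oracle <- loewe_scan_oracle(cv, cv, d, d)
    expect_equal(oracle, analytic, tolerance = 1e-3)
  }
})

test_that("root finder agrees with the brute-force effect-grid oracle", {
  set.seed(7)
  for (i in 1:10) {
    ca <- random_curve(); cb <- random_curve()
    for (j in 1:8) {
      da <- 10^runif(1, -1, 3); db <- 10^runif(1, -1, 3)
      expect_lt(abs(as.numeric(loewe_expected(ca, cb, da, db)) -
                      loewe_scan_oracle(ca, cb, da, db)), 1e-3)
    }
  }
})

test_that("doses beyond the shared effect ceiling return a saturation flag", {
  ca <- dose_response_curve(0.6, 0, 10, 2)
  cb <- dose_response_curve(1, 0, 10, 2)
  e <- loewe_expected(ca, cb, 1e5, 1e5)
  expect_equal(as.numeric(e), 0.6)
  expect_true(isTRUE(attr(e, "saturated")))
})

test_that("surfaces built under their own null have zero excess", {
  doses <- default_dose_grid()
  ca <- dose_response_curve(1, 0, 10, 1)
  cb <- dose_response_curve(1, 0, 30, 1)
  gb <- gen_matrix(doses, doses, ca, cb, null = "bliss", sd = 0, seed = 3)
  sb <- build_surface(gb, ca, cb, null_model = "bliss")
  expect_lt(max(abs(sb$excess)), 1e-9)
  expect_equal(sb$score, 0, tolerance = 1e-7)
  gl <- gen_matrix(doses, doses, ca, cb, null = "loewe", sd = 0, seed = 3)
  sl <- build_surface(gl, ca, cb, null_model = "loewe")
  expect_lt(max(abs(sl$excess)), 1e-6)
})

test_that("relabeling the drugs transposes the surface and keeps the score", {
  doses_a <- default_dose_grid()
  doses_b <- 10^seq(-0.5, 3.5, by = 0.5)
  ca <- dose_response_curve(1, 0, 15, 1.4)
  cb <- dose_response_curve(0.95, 0, 60, 0.9)
  g <- gen_matrix(doses_a, doses_b, ca, cb, null = "bliss",
                  bump_amplitude = 0.1, sd = 0, seed = 5)
  s_ab <- build_surface(g, ca, cb, null_model = "loewe")
  g_t <- dose_grid(doses_b, doses_a, t(g$effects), provenance = "synthetic")
  s_ba <- build_surface(g_t, cb, ca, null_model = "loewe")
  expect_equal(s_ba$excess, t(s_ab$excess), tolerance = 1e-9)
  expect_equal(s_ba$score, s_ab$score, tolerance = 1e-9)
})

test_that("synergy scores are weighted sums of excess on the percent scale", {
  doses <- default_dose_grid()
  ca <- dose_response_curve(1, 0, 10, 1)
  cb <- dose_response_curve(1, 0, 30, 1)
  g <- gen_matrix(doses, doses, ca, cb, null = "bliss", sd = 0, seed = 1)
  s <- build_surface(g, ca, cb, null_model = "bliss")
  # inject a constant excess of +0.1
  s$observed <- pmin(s$observed + 0.1, 1.1)  # keep unclipped for arithmetic
  s$excess <- s$observed - s$expected
  expect_equal(synergy_score(s, "uniform"), 10, tolerance = 1e-9)
  sw <- synergy_score(s, "effect_weighted")
  expect_equal(sw, 10, tolerance = 1e-9)  # constant excess: weighting moot
})

test_that("margin/curve mismatch triggers a refit with a warning", {
  doses <- c(0, default_dose_grid())
  ca <- dose_response_curve(1, 0, 10, 1)
  cb <- dose_response_curve(1, 0, 30, 1)
  g <- gen_matrix(doses, doses, ca, cb, null = "bliss", sd = 0, seed = 2)
  wrong <- dose_response_curve(1, 0, 500, 3)
  expect_warning(s <- build_surface(g, wrong, cb, null_model = "bliss"),
                 "mismatch")
  expect_lt(abs(s$curve_a$ec50 - 10), 1)
})
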