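test_that("generators are pure functions of their spec", {
  a <- gen_curves(n_curves = 3, sd = 5, seed = 17)
  b <- gen_curves(n_curves = 3, sd = 5, seed = 17)
  expect_identical(a, b)
  g1 <- gen_matrix(sd = 0.05, seed = 17)
  g2 <- gen_matrix(sd = 0.05, seed = 17)
  expect_identical(g1$effects, g2$effects)
  c1 <- gen_cohort(noise_sd = 0.1, slope_jitter_sd = 0.05, seed = 17)
  c2 <- gen_cohort(noise_sd = 0.1, slope_jitter_sd = 0.05, seed = 17)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  # generators do not disturb the global RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(gen_curves(seed = 3)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("zero noise reproduces the generating truth exactly", {
  cur <- gen_curves(n_curves = 2, ec50 = c(50, 500), sd = 0, seed = 1)
  truth <- attr(cur, "truth")
  for (i in 1:2) {
    sub <- cur[cur$curve == i, ]
    expect_equal(sub$effect,
                 fourpl(sub$dose, truth$top[i], truth$bottom[i],
                        truth$ec50[i], truth$hill[i]))
  }
  ch <- gen_cohort(groups = c(g = 0.2), n = 2, seed = 1)
  expect_equal(ch$volume, 150 * 2^(0.2 * ch$day))
})

test_that("generated artifacts carry machine-readable truth metadata", {
  g <- gen_matrix(null = "bliss", bump_amplitude = 0.1, sd = 0.02, seed = 5)
  tr <- attr(g, "truth")
  expect_equal(tr$null, "bliss")
  expect_equal(tr$seed, 5)
  expect_gt(tr$bump_mass, 0)
  ch <- gen_cohort(slope_jitter_sd = 0.02, seed = 5)
  tc <- attr(ch, "truth")
  expect_equal(nrow(tc$animals), 20)
  expect_true(all(c("true_slope", "doubling_days") %in% names(tc$animals)))
})

test_that("degenerate generator specs are rejected", {
  expect_error(gen_curves(doses = c(10, 10)), "degenerate")
  expect_error(gen_curves(sd = -1), "non-negative")
  expect_error(gen_matrix(sd = -0.1), "non-negative")
  expect_error(gen_cohort(groups = c(0.1)), "named")
  expect_error(gen_cohort(n = 0), "invalid")
})

test_that("a synergy bump overflowing the effect scale raises a warning", {
  ca <- dose_response_curve(1, 0, 1, 2)
  expect_warning(gen_matrix(curve_a = ca, curve_b = ca, null = "bliss",
                            bump_amplitude = 0.5, seed = 1), "above 1")
})

test_that("the injected bump mass is recovered by the uniform score", {
  ca <- dose_response_curve(0.8, 0, 10, 1)
  cb <- dose_response_curve(0.8, 0, 30, 1)
  scores <- vapply(1:50, function(s) {
    g <- gen_matrix(curve_a = ca, curve_b = cb, null = "bliss",
                    bump_amplitude = 0.15, sd = 0.02, seed = s)
    build_surface(g, ca, cb, null_model = "bliss")$score
  }, numeric(1))
  g1 <- gen_matrix(curve_a = ca, curve_b = cb, null = "bliss",
                   bump_amplitude = 0.15, sd = 0.02, seed = 1)
  expected <- 100 * attr(g1, "truth")$bump_mass / attr(g1, "truth")$n_cells
  expect_lt(abs(mean(scores) - expected), 0.2 * expected)
})

test_that("two vehicle-like groups give near-zero tumor growth inhibition", {
  ch <- gen_cohort(groups = c(a = 0.2, b = 0.2), n = 10,
                   noise_sd = 0.05, seed = 31)
  expect_lt(abs(tgi(ch, "a", "b")$tgi), 5)
})

test_that("the death process truncates measurements and records death days", {
  ch <- gen_cohort(groups = c(g = 0.1), n = 20, death_rate = 0.08, seed = 7)
  died <- unique(ch$animal[!is.na(ch$death_day)])
  expect_gt(length(died), 0)
  for (a in died) {
    sub <- ch[ch$animal == a, ]
    expect_true(all(sub$day <= sub$death_day[1]))
  }
})
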