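test_that("noiseless exponential growth recovers exact slopes", {
  ch <- gen_cohort(groups = c(g = 0.2), n = 4, seed = 1)
  fit <- fit_growth(ch)
  expect_true(all(abs(fit$animals$slope - 0.2) < 1e-10))
  flat <- gen_cohort(groups = c(g = 0), n = 3, seed = 1)
  expect_true(all(abs(fit_growth(flat)$animals$slope) < 1e-10))
})

test_that("group mean slope is recovered from noisy cohorts", {
  ch <- gen_cohort(groups = c(g = 0.2), n = 10, noise_sd = 0.1, seed = 21)
  fit <- fit_growth(ch)
  g <- fit$groups
  expect_lt(abs(g$slope - 0.2), 0.02)
})

test_that("animals with too few timepoints are excluded with a warning", {
  ch <- gen_cohort(groups = c(g = 0.1), n = 3, seed = 2)
  short <- as.data.frame(ch)
  short <- short[!(short$animal == "g_1" & short$day > 3.5), ]
  expect_warning(fit <- fit_growth(tumor_cohort(short)), "excluded")
  expect_false("g_1" %in% fit$animals$animal)
})

test_that("%TGI matches the analytic value for exponential growth", {
  ch <- gen_cohort(groups = c(vehicle = 0.2, treated = 0),
                   n = 6, days = seq(0, 20, by = 2), seed = 1)
  res <- tgi(ch, "treated", "vehicle", window = c(0, 20))
  # AUC/day of 2^(0.2 t) over [0, 20] is (2^4 - 1) / (4 log 2); flat = 1
  analytic <- 100 * (1 - 1 / ((2^4 - 1) / (4 * log(2))))
  expect_equal(res$tgi, analytic, tolerance = 0.5)
  # identical groups: zero inhibition
  ch2 <- gen_cohort(groups = c(a = 0.15, b = 0.15), n = 5, seed = 3)
  expect_equal(tgi(ch2, "a", "b")$tgi, 0, tolerance = 1e-8)
})

test_that("%TGI is invariant to volume rescaling and ranks regression higher", {
  ch <- gen_cohort(groups = c(vehicle = 0.2, static = 0, regress = -0.1),
                   n = 5, noise_sd = 0.05, seed = 9)
  t_reg <- tgi(ch, "regress", "vehicle")$tgi
  t_stat <- tgi(ch, "static", "vehicle")$tgi
  expect_gt(t_reg, t_stat)
  expect_lt(t_reg, 100)  # raw volume AUC stays positive
  scaled <- as.data.frame(ch)
  scaled$volume <- scaled$volume * 3.7
  expect_equal(tgi(tumor_cohort(scaled), "regress", "vehicle")$tgi, t_reg,
               tolerance = 1e-9)
})

test_that("PFS events fall exactly at doubling for clean exponentials", {
  ch <- gen_cohort(groups = c(g = 1 / 5), n = 5, seed = 1)
  res <- pfs(ch, threshold_fold = 2)
  expect_true(all(abs(res$events$time - 5) < 1e-9))
  expect_true(all(res$events$event == 1))
  expect_equal(unname(res$medians["g"]), 5, tolerance = 1e-9)
})

test_that("death before doubling is the PFS event", {
  df <- data.frame(animal = "a1", group = "g", day = c(0, 3.5),
                   volume = c(100, 120), death_day = 3)
  res <- pfs(tumor_cohort(df))
  expect_equal(res$events$time, 3)
  expect_equal(res$events$cause, "death")
})

test_that("raising the progression threshold never shortens event times", {
  ch <- gen_cohort(groups = c(g = 0.15), n = 8, noise_sd = 0.05,
                   slope_jitter_sd = 0.03, seed = 12)
  t2 <- pfs(ch, threshold_fold = 2)$events
  t3 <- pfs(ch, threshold_fold = 3)$events
  m <- merge(t2, t3, by = "animal")
  progressed <- m$event.x == 1 & m$event.y == 1
  expect_true(all(m$time.y[progressed] >= m$time.x[progressed] - 1e-9))
})

test_that("animals that never progress are censored at last measurement", {
  ch <- gen_cohort(groups = c(slow = 0.01), n = 3, seed = 4)
  res <- pfs(ch)
  expect_true(all(res$events$event == 0))
  expect_true(all(res$events$time == 21))
})

test_that("trapezoid AUC matches the analytic exponential integral closely", {
  days <- seq(0, 21, by = 1)
  curve <- 2^(0.18 * days)
  num <- mapkdual:::.trapz(days, curve)
  ana <- (2^(0.18 * 21) - 1) / (0.18 * log(2))
  expect_equal(num / ana, 1, tolerance = 0.005)
})
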