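test_that("feedback flags gate the corresponding reactions", {
  p <- fx_params()
  net0 <- fx_net_no_feedback()
  rn <- colnames(net0$S)
  expect_false(any(grepl("dusp_", rn)))
  expect_false(any(grepl("spry_", rn)))
  expect_false(any(grepl("feedback", rn)))
  net <- fx_net()
  rn <- colnames(net$S)
  expect_true(all(c("dusp_synthesis", "spry_synthesis",
                    "raf_feedback_phospho", "mek_feedback_phospho") %in% rn))
})

test_that("both inhibitors register binding reactions for every target form", {
  rn <- colnames(fx_net()$S)
  for (f in c("MEK", "pMEK", "MEKf"))
    expect_true(all(c(paste0("bind_mek_", f), paste0("unbind_mek_", f)) %in% rn))
  for (f in c("ERK", "pERK", "ppERK"))
    expect_true(all(c(paste0("bind_erk_", f), paste0("unbind_erk_", f)) %in% rn))
})

test_that("invalid configurations are rejected", {
  p <- fx_params()
  inh <- list(inhibitor_spec("MEK", 1, 1), inhibitor_spec("MEK", 2, 2))
  expect_error(build_network(p, feedback_config(), inh), "duplicate")
  bad <- p
  bad$totals$MEK <- 0
  expect_error(build_network(bad), "positive")
  expect_error(feedback_config(fb_dusp = NA), "logical")
})

test_that("stoichiometry conserves every protein moiety structurally", {
  net <- fx_net()
  for (members in net$moieties) {
    colsum <- colSums(net$S[members, , drop = FALSE])
    expect_true(all(abs(colsum) < 1e-12))
  }
})

test_that("no input means no pathway output", {
  p <- fx_params()
  p$totals$GS <- 0
  net <- build_network(p)
  expect_lt(net$vehicle_output, 1e-6 * p$totals$ERK)
})

test_that("trajectories conserve protein totals and are deterministic", {
  net <- fx_net()
  tr1 <- simulate_network(net, 30, 100, t_end = 72, n_points = 73)
  expect_lt(max(conservation_drift(tr1)), 1e-6)
  expect_true(all(tr1$conc > -1e-9))
  tr2 <- simulate_network(net, 30, 100, t_end = 72, n_points = 73)
  expect_identical(tr1$conc, tr2$conc)
})

test_that("dose and time arguments are validated", {
  net <- fx_net()
  expect_error(simulate_network(net, -1, 0), "non-negative")
  expect_error(simulate_network(net, 0, 0, t_end = 0), "positive")
  expect_error(steady_state(net, -5, 0), "non-negative")
})

test_that("the steady state is unique from perturbed initial conditions", {
  # perturb within each conservation class (moiety totals unchanged)
  net <- fx_net()
  set.seed(8)
  shuffle <- function(y) {
    for (members in net$moieties) {
      w <- runif(length(members))
      y[members] <- sum(y[members]) * w / sum(w)
    }
    y[c("DUSP", "SPRY")] <- y[c("DUSP", "SPRY")] * runif(2, 0.2, 3)
    y
  }
  s1 <- steady_state(net, init = shuffle(net$vehicle_ss))
  s2 <- steady_state(net, init = shuffle(net$vehicle_ss))
  expect_true(s1$converged && s2$converged)
  expect_equal(s1$output / s2$output, 1, tolerance = 1e-6)
  expect_equal(s1$state, s2$state, tolerance = 1e-5)
})

test_that("saturating MEKi without transcriptional feedback silences output", {
  net <- fx_net_no_transcription()
  kd <- net$inhibitors$mek$kd
  ss <- steady_state(net, dose_mek = 100 * kd)
  expect_true(ss$converged)
  expect_lt(ss$output, 0.01 * net$vehicle_output)
})

test_that("the decoupled network is sized to the coupled vehicle output", {
  net_c <- fx_net()
  net_d <- fx_net_decoupled()
  expect_equal(net_d$vehicle_output / net_c$vehicle_output, 1,
               tolerance = 0.01)
  # SPRY cannot influence output when RAF is decoupled from RAS: with
  # the constitutive rate held fixed, rescaling the SPRY inhibition
  # constant leaves the output untouched
  p2 <- fx_params()
  p2$rates$k_spry <- p2$rates$k_spry * 100
  net_d2 <- mapkdual:::.assemble_network(p2, feedback_config(ras_coupled = FALSE),
                                         default_inhibitors(p2),
                                         k_rafconst = net_d$k_rafconst)
  ss2 <- mapkdual:::.solve_steady(net_d2, mapkdual:::.dosed_k(net_d2, 0, 0),
                                  net_d2$init)
  expect_equal(ss2$state[net_d2$idx["ppERK"]] / net_d$vehicle_output, 1,
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("ERK-stage steady state matches the algebraic two-step solution", {
  # reduced sub-network oracle: with free pMEK and the phosphatase pool
  # fixed at their steady-state values, the distributive two-step cycle
  # with a shared saturable phosphatase has a closed-form fixed point
  net <- fx_net()
  r <- fx_params()$rates
  ss <- fx_net()$vehicle_ss
  P <- ss["pMEK"]
  V <- r$k_erkdp + r$k_dusp * ss["DUSP"]
  Tot <- fx_params()$totals$ERK
  a <- r$k_erkp * P
  f <- function(x) {
    load <- Tot * (x + x^2) / (1 + x + x^2)
    x - a * (r$km_erk + load) / V
  }
  x <- uniroot(f, c(1e-8, 1e4), tol = 1e-12)$root
  pp_pred <- Tot * x^2 / (1 + x + x^2)
  expect_equal(unname(ss["ppERK"] / pp_pred), 1, tolerance = 1e-6)
})

test_that("trajectory export writes a tidy table with metadata sidecar", {
  net <- fx_net()
  tr <- simulate_network(net, 10, 0, t_end = 6, n_points = 13)
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  long <- read.csv(path)
  expect_setequal(names(long), c("time_h", "species", "concentration_nM"))
  expect_equal(nrow(long), 13 * length(net$species))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$dose_mek_nM, 10)
  expect_equal(meta$integrator$rtol, 1e-8)
  unlink(c(path, paste0(path, ".json")))
})
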