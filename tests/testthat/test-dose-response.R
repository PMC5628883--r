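test_that("the viability link is anchored at vehicle and at full suppression", {
  link <- viability_link(emax = 0.9, k_rel = 0.25, hill = 2)
  expect_equal(viability_from_output(1, link), 1)
  expect_equal(viability_from_output(0, link), 0.1)
  expect_error(viability_from_output(-0.1, link), "non-negative")
  # monotone non-decreasing in relative output
  s <- seq(0, 1, by = 0.01)
  v <- viability_from_output(s, link)
  expect_true(all(diff(v) >= -1e-12))
})

test_that("half-maximal kill occurs at k_rel when vehicle output dominates", {
  # exact half-kill at s = k_rel holds in the limit k_rel << 1
  link <- viability_link(emax = 1, k_rel = 1e-4, hill = 1)
  expect_equal(viability_from_output(1e-4, link), 0.5, tolerance = 1e-3)
})

test_that("matrix margins equal independently simulated single agents", {
  net <- fx_net()
  link <- fx_link()
  doses <- c(0, 10, 100)
  g <- run_matrix(net, doses, doses, link)
  ma <- run_single_agent(net, "MEK", doses, link)
  mb <- run_single_agent(net, "ERK", doses, link)
  expect_identical(unname(g$effects[, 1]), ma$effect)
  expect_identical(unname(g$effects[1, ]), mb$effect)
  expect_equal(g$effects[1, 1], 0, tolerance = 1e-9)
  expect_true(g$monotone)
})

test_that("saturating both drugs drives the effect to the link ceiling", {
  net <- fx_net()
  link <- fx_link()
  s <- mapkdual:::.metric_from_sim(net, 1e5, 1e5, link)
  eff <- 1 - viability_from_output(s, link)
  expect_equal(eff, link$emax, tolerance = 0.01 * link$emax)
})

test_that("the acute output-EC50 halves the output nadir", {
  net <- fx_net()
  ec <- fx_ec50()
  tr <- fx_traj_mek_ec50()
  expect_equal(min(tr$output) / net$vehicle_output, 0.5, tolerance = 0.01)
  tr_e <- simulate_network(net, 0, ec["erk"], t_end = 6, n_points = 61)
  expect_equal(min(tr_e$output) / net$vehicle_output, 0.5, tolerance = 0.01)
})
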