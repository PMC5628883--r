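test_that("rebound index summarizes suppression-and-recovery shape", {
  expect_equal(rebound_index(c(10, 8, 6, 4, 2)), 0)
  expect_equal(rebound_index(c(10, 2, 5, 8, 10)), 1)
  expect_equal(rebound_index(c(10, 4, 4, 7)), 0.5)
  flat <- rebound_index(c(10, 9.99, 10, 10))
  expect_true(is.na(flat))
  expect_true(isTRUE(attr(flat, "undefined")))
})

test_that("vehicle transcript levels stay at 100% of baseline", {
  net <- fx_net()
  tr <- simulate_network(net, 0, 0, t_end = 24, n_points = 25)
  for (t in c(3, 12, 24)) {
    expect_equal(transcript_recovery(tr, "DUSP", t), 100, tolerance = 1e-3)
    expect_equal(transcript_recovery(tr, "SPRY", t), 100, tolerance = 1e-3)
  }
})

test_that("fully suppressed synthesis decays by first-order kinetics", {
  net <- fx_net()
  tr <- simulate_network(net, 2000, 2000, t_end = 12, n_points = 49)
  half_life <- log(2) / fx_params()$rates$kdeg_dusp
  for (t in c(2, 4, 8)) {
    expect_equal(transcript_recovery(tr, "DUSP", t),
                 100 * 2^(-t / half_life), tolerance = 0.05 * 100)
  }
  hl_spry <- log(2) / fx_params()$rates$kdeg_spry
  expect_equal(transcript_recovery(tr, "SPRY", 4),
               100 * 2^(-4 / hl_spry), tolerance = 5)
})

test_that("inert inhibitors leave every regimen at vehicle", {
  p <- fx_params()
  inert <- list(inhibitor_spec("MEK", kon = 1e-10, koff = 1e4),
                inhibitor_spec("ERK", kon = 1e-10, koff = 1e4))
  net <- build_network(p, feedback_config(), inert)
  cmp <- compare_fractional_combo(net, 100, 100)
  expect_true(all(abs(cmp$auc_rel - 1) < 1e-3))
})

test_that("transcriptional feedback is required for reactivation", {
  net_nt <- fx_net_no_transcription()
  ec <- output_ec50(net_nt, "MEK")
  tr <- simulate_network(net_nt, ec, 0)
  reb <- rebound_index(tr)
  expect_true(is.na(reb) || reb < 0.05)
})
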