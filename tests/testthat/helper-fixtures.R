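# Shared fixtures. The calibrated networks are expensive to build (the
# decoupled variant runs a sizing root-find over steady states), so they
# are constructed lazily and memoized for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

fx_params <- function() fx("params", default_params)
fx_link <- function() fx("link", function() default_link(fx_params()))

fx_net <- function() fx("net", function() build_network(fx_params()))

fx_net_decoupled <- function() fx("net_decoupled", function()
  build_network(fx_params(), feedback_config(ras_coupled = FALSE)))

# transcriptional feedbacks (DUSP, SPRY) disabled, phospho feedback kept
fx_net_no_transcription <- function() fx("net_nt", function()
  build_network(fx_params(), feedback_config(fb_dusp = FALSE, fb_spry = FALSE)))

fx_net_no_feedback <- function() fx("net_nofb", function()
  build_network(fx_params(), feedback_config(FALSE, FALSE, FALSE)))

fx_ec50 <- function() fx("ec50", function()
  c(mek = output_ec50(fx_net(), "MEK"), erk = output_ec50(fx_net(), "ERK")))

fx_traj_mek_ec50 <- function() fx("traj_mek", function()
  simulate_network(fx_net(), fx_ec50()["mek"], 0))

# random fraction-scale 4PL curves for property tests
random_curve <- function(ec50_range = c(3, 100), hill_range = c(0.5, 3),
                         top_range = c(0.9, 1)) {
  dose_response_curve(
    top = runif(1, top_range[1], top_range[2]), bottom = 0,
    ec50 = 10^runif(1, log10(ec50_range[1]), log10(ec50_range[2])),
    hill = runif(1, hill_range[1], hill_range[2]))
}

# brute-force Loewe oracle: scan a dense effect grid for the value that
# best satisfies the dose-equivalence equation (independent of the
# root-finding implementation)
loewe_scan_oracle <- function(curve_a, curve_b, dose_a, dose_b,
                              n_grid = 1e4) {
  lo <- max(curve_a$bottom, curve_b$bottom)
  hi <- min(curve_a$top, curve_b$top)
  e <- seq(lo + (hi - lo) * 1e-9, hi - (hi - lo) * 1e-9, length.out = n_grid)
  da <- invert_curve(curve_a, e)
  db <- invert_curve(curve_b, e)
  f <- dose_a / da + dose_b / db - 1
  if (all(f > 0, na.rm = TRUE)) return(hi)       # saturated: ceiling
  e[which.min(abs(f))]
}
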