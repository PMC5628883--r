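#' Simulate the cascade under clamped inhibitor doses
#'
#' Deterministic stiff integration (lsoda, relative tolerance 1e-8,
#' absolute tolerance 1e-10 nM) from the pre-equilibrated vehicle steady
#' state, with free drug concentrations clamped constant (no depletion).
#'
#' @param network a [build_network()] object.
#' @param dose_mek,dose_erk clamped free inhibitor concentrations (nM).
#' @param t_end end of the time grid (h).
#' @param n_points number of output time points.
#' @return An object of class `mapk_trajectory`: a list with `time` (h),
#'   `conc` (time-by-species nM matrix), `output` (pathway output = free,
#'   non-drug-bound ppERK), `craf` (active, non-feedback-phosphorylated
#'   RAF), `dusp`, `spry`, the doses, vehicle reference levels, and
#'   per-moiety conservation drift diagnostics.
#' @export
simulate_network <- function(network, dose_mek = 0, dose_erk = 0,
                             t_end = 72, n_points = 289) {
  stopifnot(inherits(network, "reaction_network"))
  if (dose_mek < 0 || dose_erk < 0) stop("doses must be non-negative")
  if (t_end <= 0) stop("`t_end` must be positive")
  times <- seq(0, t_end, length.out = n_points)
  k <- .dosed_k(network, dose_mek, dose_erk)
  rhs <- .network_rhs(network)
  sol <- deSolve::lsoda(network$vehicle_ss, times = times, func = rhs,
                        parms = list(k = k), rtol = 1e-8, atol = 1e-10,
                        maxsteps = 50000)
  istate <- attr(sol, "istate")[1]
  if (istate < 0 || nrow(sol) < n_points) {
    bad <- sol[nrow(sol), ]
    stop(sprintf(paste0("integration failed (istate %d) at t = %.3f h; ",
                        "state: %s"), istate, bad[1],
                 paste(sprintf("%s=%.3g", network$species, bad[-1]),
                       collapse = ", ")))
  }
  conc <- sol[, -1, drop = FALSE]
  colnames(conc) <- network$species

  drift <- vapply(network$moieties, function(members) {
    tot <- rowSums(conc[, members, drop = FALSE])
    ref <- tot[1]
    max(abs(tot - ref)) / ref
  }, numeric(1))

  structure(list(
    time = times, conc = conc,
    output = pmax(conc[, "ppERK"], 0),
    craf = pmax(conc[, "RAFa"], 0),
    dusp = pmax(conc[, "DUSP"], 0), spry = pmax(conc[, "SPRY"], 0),
    dose_mek = dose_mek, dose_erk = dose_erk,
    vehicle_output = network$vehicle_output,
    vehicle_craf = network$vehicle_craf,
    vehicle_ss = network$vehicle_ss,
    config = network$config, totals = network$params$totals,
    drift = drift), class = "mapk_trajectory")
}

#' @export
print.mapk_trajectory <- function(x, ...) {
  cat(sprintf("MAPK trajectory: 0-%g h, %d points, MEKi %g nM, ERKi %g nM\n",
              max(x$time), length(x$time), x$dose_mek, x$dose_erk))
  cat(sprintf("  pathway output: vehicle %.3g nM, final %.3g nM (%.1f%%)\n",
              x$vehicle_output, tail(x$output, 1),
              100 * tail(x$output, 1) / x$vehicle_output))
  cat(sprintf("  max conservation drift: %.2e\n", max(x$drift)))
  invisible(x)
}

#' Pathway output series of a trajectory
#'
#' The model's pharmacodynamic readout: free, non-drug-bound ppERK (nM),
#' a proxy for p-p90RSK-level pathway output.
#'
#' @param traj an [simulate_network()] trajectory.
#' @return Numeric vector along `traj$time`.
#' @export
pathway_output <- function(traj) {
  stopifnot(inherits(traj, "mapk_trajectory"))
  traj$output
}

#' Conservation drift of a trajectory
#'
#' Maximum relative drift of each conserved protein total (sum over all
#' free/phospho/feedback/drug-bound forms) along the trajectory.
#'
#' @param traj an [simulate_network()] trajectory.
#' @return Named numeric vector (one entry per conserved moiety).
#' @export
conservation_drift <- function(traj) {
  stopifnot(inherits(traj, "mapk_trajectory"))
  traj$drift
}

#' Active-CRAF fold-change series
#'
#' Active RAF (`RAFa`, excluding feedback-phosphorylated forms) normalized
#' to the vehicle steady state, so the vehicle fold-change is identically 1.
#' Inhibitor treatment de-represses upstream signaling through loss of
#' SPRY- and phospho-mediated feedback, which raises this fold-change.
#'
#' @param traj an [simulate_network()] trajectory from a RAS-coupled network.
#' @return Numeric fold-change vector along `traj$time`.
#' @export
craf_activity <- function(traj) {
  stopifnot(inherits(traj, "mapk_trajectory"))
  if (!isTRUE(traj$config$ras_coupled))
    stop("CRAF activity is defined for RAS-coupled networks")
  if (traj$vehicle_craf <= 1e-12)
    stop("vehicle active-RAF level is zero; fold-change undefined")
  traj$craf / traj$vehicle_craf
}

#' Time-integrated pathway output
#'
#' Trapezoid integral of the pathway output over the trajectory time grid
#' (nM h), the default exposure metric feeding the viability link.
#'
#' @param traj an [simulate_network()] trajectory.
#' @return Scalar nM h.
#' @export
output_auc <- function(traj) {
  stopifnot(inherits(traj, "mapk_trajectory"))
  .trapz(traj$time, traj$output)
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Export a trajectory as a tidy table
#'
#' Writes a delimited table with columns `time_h`, `species`,
#' `concentration_nM`, plus a JSON metadata sidecar (`<path>.json`)
#' recording the feedback configuration, doses, integrator tolerances and
#' units.
#'
#' @param traj an [simulate_network()] trajectory.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "mapk_trajectory"))
  long <- data.frame(
    time_h = rep(traj$time, times = ncol(traj$conc)),
    species = rep(colnames(traj$conc), each = nrow(traj$conc)),
    concentration_nM = as.vector(traj$conc))
  utils::write.csv(long, path, row.names = FALSE)
  meta <- list(
    units = list(time = "h", concentration = "nM"),
    dose_mek_nM = traj$dose_mek, dose_erk_nM = traj$dose_erk,
    config = unclass(traj$config),
    integrator = list(method = "lsoda", rtol = 1e-8, atol = 1e-10),
    max_conservation_drift = max(traj$drift))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
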