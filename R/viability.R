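# Mapping model pathway output to fractional cell viability. The pathway
# model ends at ppERK; viability is linked to pathway output through a
# saturating Hill transform of the output relative to vehicle, normalized
# so that vehicle output maps exactly to viability 1 and fully suppressed
# output maps to the kill floor 1 - emax.

#' Viability link function specification
#'
#' Defines how a pathway-output exposure metric maps to fractional
#' viability. With `s` the output metric relative to vehicle (1 = vehicle,
#' 0 = complete suppression) and `g(s) = k_rel^hill / (k_rel^hill +
#' s^hill)`, viability is
#' `V(s) = 1 - emax * (g(s) - g(1)) / (g(0) - g(1))`,
#' a monotone non-decreasing function of `s` with `V(1) = 1` exactly and
#' `V(0) = 1 - emax` exactly. For `k_rel` well below 1 this reduces to a
#' plain Hill response in the output with half-kill near `s = k_rel`.
#'
#' @param emax maximal kill fraction in \[0, 1\].
#' @param k_rel output level (as a fraction of vehicle output) giving
#'   approximately half-maximal kill.
#' @param hill Hill slope of the link (> 0).
#' @param mode output metric: `"auc"` (time-integrated free ppERK over the
#'   simulated window, default) or `"steady_state"` (post-treatment
#'   steady-state free ppERK).
#' @return An object of class `viability_link`.
#' @export
viability_link <- function(emax = 0.95, k_rel = 0.25, hill = 2,
                           mode = c("auc", "steady_state")) {
  mode <- match.arg(mode)
  if (emax < 0 || emax > 1) stop("`emax` must be in [0, 1]")
  if (k_rel <= 0) stop("`k_rel` must be positive")
  if (hill <= 0) stop("`hill` must be positive")
  structure(list(emax = emax, k_rel = k_rel, hill = hill, mode = mode),
            class = "viability_link")
}

#' Default viability link from a parameter file
#'
#' @param params a parameter list with a `link` section (see
#'   [default_params()]).
#' @return A [viability_link()].
#' @export
default_link <- function(params = default_params()) {
  l <- params$link
  if (is.null(l)) return(viability_link())
  viability_link(emax = l$emax, k_rel = l$k_rel, hill = l$hill,
                 mode = l$mode %||% "auc")
}

#' Fractional viability from relative pathway output
#'
#' @param output pathway-output metric (non-negative), on the scale set by
#'   `output_vehicle`.
#' @param link a [viability_link()].
#' @param output_vehicle the vehicle (untreated) value of the same metric;
#'   defaults to 1, i.e. `output` already relative.
#' @return Fractional viability in `[1 - emax, 1]` (vectorized).
#' @export
viability_from_output <- function(output, link = viability_link(),
                                  output_vehicle = 1) {
  stopifnot(inherits(link, "viability_link"))
  if (any(output < 0)) stop("`output` must be non-negative")
  if (output_vehicle <= 0) stop("`output_vehicle` must be positive")
  s <- output / output_vehicle
  g <- function(u) link$k_rel^link$hill / (link$k_rel^link$hill + u^link$hill)
  v <- 1 - link$emax * (g(s) - g(1)) / (g(0) - g(1))
  pmin(pmax(v, 1 - link$emax), 1)
}

.metric_from_sim <- function(network, dose_mek, dose_erk, link, t_end = 72) {
  if (link$mode == "steady_state") {
    ss <- steady_state(network, dose_mek, dose_erk)
    return(ss$output / network$vehicle_output)
  }
  traj <- simulate_network(network, dose_mek, dose_erk, t_end = t_end,
                           n_points = 145)
  output_auc(traj) / (network$vehicle_output * t_end)
}

#' Single-agent response curve from the model
#'
#' Simulates one inhibitor over a dose ladder (other drug at 0) and maps
#' output to fractional effect (`1 - viability`) through the link.
#'
#' @param network a [build_network()] object with the inhibitor registered.
#' @param target `"MEK"` or `"ERK"`.
#' @param doses dose vector (nM).
#' @param link a [viability_link()].
#' @param t_end simulated exposure (h) for the AUC metric.
#' @return A data frame with `dose` and fractional `effect`.
#' @export
run_single_agent <- function(network, target = c("MEK", "ERK"), doses,
                             link = viability_link(), t_end = 72) {
  target <- match.arg(target)
  eff <- vapply(doses, function(d) {
    s <- if (target == "MEK") .metric_from_sim(network, d, 0, link, t_end)
         else .metric_from_sim(network, 0, d, link, t_end)
    1 - viability_from_output(s, link)
  }, numeric(1))
  data.frame(dose = doses, effect = eff)
}

#' Run a two-drug dose matrix through the model
#'
#' One simulation per dose pair (MEK inhibitor on the A axis, ERK inhibitor
#' on the B axis), mapping pathway output to fractional effect through the
#' viability link. Zero doses are allowed, so grids with a leading zero
#' carry their single-agent margins; those margins equal independently
#' simulated single-agent responses exactly (same solver settings).
#'
#' @param network a [build_network()] object with both inhibitors
#'   registered.
#' @param doses_a MEK-inhibitor dose axis (nM).
#' @param doses_b ERK-inhibitor dose axis (nM).
#' @param link a [viability_link()].
#' @param t_end simulated exposure (h) for the AUC metric.
#' @return A [dose_grid()] with provenance `"simulated"`.
#' @export
run_matrix <- function(network, doses_a = default_dose_grid(),
                       doses_b = default_dose_grid(),
                       link = viability_link(), t_end = 72) {
  stopifnot(inherits(network, "reaction_network"))
  if (is.null(network$inhibitors$mek) || is.null(network$inhibitors$erk))
    stop("network must have both a MEK and an ERK inhibitor registered")
  eff <- matrix(NA_real_, length(doses_a), length(doses_b))
  for (i in seq_along(doses_a)) for (j in seq_along(doses_b)) {
    s <- tryCatch(
      .metric_from_sim(network, doses_a[i], doses_b[j], link, t_end),
      error = function(e)
        stop(sprintf("simulation failed at dose pair (%g, %g) nM: %s",
                     doses_a[i], doses_b[j], conditionMessage(e))))
    eff[i, j] <- 1 - viability_from_output(s, link)
  }
  mono <- all(diff(eff) >= -1e-6) && all(t(diff(t(eff))) >= -1e-6)
  g <- dose_grid(doses_a, doses_b, eff, provenance = "simulated",
                 drug_a = "MEKi", drug_b = "ERKi")
  g$monotone <- mono
  if (!mono) warning("response grid is not monotone along both dose axes")
  g
}

#' Model output-EC50 of an inhibitor
#'
#' The single-agent reference dose for reactivation and fractional-dose
#' analyses. By default (`response = "acute"`) this is the acute
#' (pre-adaptation) EC50: the dose at which the pathway-output nadir over
#' the first hours of exposure is half the vehicle output -- the model
#' analog of a cellular EC50 measured at the early pharmacodynamic trough,
#' before feedback relief rebuilds the output. The dose halving the fully
#' adapted steady-state output is available via
#' `response = "steady_state"`; note that at that dose the 72-h output is
#' half-vehicle by construction, so rebound indices there are capped below
#' 0.5.
#'
#' @param network a [build_network()] object.
#' @param target `"MEK"` or `"ERK"`.
#' @param response `"acute"` (nadir-based, default) or `"steady_state"`.
#' @param interval log10-dose search interval (nM).
#' @param t_acute window (h) over which the acute nadir is taken.
#' @return Dose in nM.
#' @export
output_ec50 <- function(network, target = c("MEK", "ERK"),
                        response = c("acute", "steady_state"),
                        interval = c(-2, 4), t_acute = 6) {
  target <- match.arg(target)
  response <- match.arg(response)
  f <- function(ld) {
    d <- 10^ld
    out <- if (response == "steady_state") {
      ss <- if (target == "MEK") steady_state(network, d, 0)
            else steady_state(network, 0, d)
      ss$output
    } else {
      traj <- if (target == "MEK")
        simulate_network(network, d, 0, t_end = t_acute, n_points = 61)
      else simulate_network(network, 0, d, t_end = t_acute, n_points = 61)
      min(traj$output)
    }
    out / network$vehicle_output - 0.5
  }
  10^uniroot(f, interval, tol = 1e-6)$root
}
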