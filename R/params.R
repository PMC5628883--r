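#' Feedback configuration for the MAPK cascade model
#'
#' Selects which of the three canonical negative feedback loops are wired
#' into the reaction network, and whether RAF activation is coupled to
#' Ras-GTP (the KRAS-mutant setting) or constitutive (a BRAF-mutant mimic
#' in which the RAF complex is dissociated from RAS).
#'
#' @param fb_phospho enable ppERK-mediated inhibitory phosphorylation of
#'   MEK and of CRAF-containing RAF. The CRAF arm of this feedback acts on
#'   the RAS-coupled activation cycle only; in a decoupled network the
#'   constitutively active RAF mimics monomeric mutant BRAF, which is not
#'   subject to ERK-dependent dimer disruption, so only the MEK arm remains.
#' @param fb_dusp enable ppERK-induced DUSP synthesis and DUSP-catalyzed
#'   ERK dephosphorylation.
#' @param fb_spry enable ppERK-induced SPRY synthesis and SPRY inhibition
#'   of Grb2-SOS-driven RAS activation.
#' @param ras_coupled when `TRUE` RAF activation requires Ras-GTP; when
#'   `FALSE` RAF activates constitutively at a first-order rate sized so
#'   that the vehicle steady-state pathway output matches the coupled
#'   network (see [build_network()]).
#' @return An object of class `feedback_config`.
#' @export
feedback_config <- function(fb_phospho = TRUE, fb_dusp = TRUE,
                            fb_spry = TRUE, ras_coupled = TRUE) {
  flags <- list(fb_phospho = fb_phospho, fb_dusp = fb_dusp,
                fb_spry = fb_spry, ras_coupled = ras_coupled)
  ok <- vapply(flags, function(x) is.logical(x) && length(x) == 1L && !is.na(x),
               logical(1))
  if (!all(ok)) stop("all feedback_config fields must be single logical values")
  structure(flags, class = "feedback_config")
}

#' Inhibitor specification
#'
#' Reversible mass-action binding of a small-molecule inhibitor to every
#' phosphoform of its target kinase with state-independent affinity.
#' Drug-bound forms keep their phosphorylation state and remain substrates
#' for (de)phosphorylation, but are catalytically dead; drug-bound ppERK
#' contributes neither to pathway output nor to any feedback drive.
#'
#' @param target `"MEK"` or `"ERK"`.
#' @param kon association rate, 1/(nM h).
#' @param koff dissociation rate, 1/h. The dissociation constant is
#'   `Kd = koff/kon` (nM).
#' @return An object of class `inhibitor_spec`.
#' @export
inhibitor_spec <- function(target = c("MEK", "ERK"), kon, koff) {
  target <- match.arg(target)
  if (!is.numeric(kon) || length(kon) != 1L || kon <= 0)
    stop("`kon` must be a single positive number")
  if (!is.numeric(koff) || length(koff) != 1L || koff <= 0)
    stop("`koff` must be a single positive number")
  structure(list(target = target, kon = kon, koff = koff, kd = koff / kon),
            class = "inhibitor_spec")
}

.param_rate_names <- c(
  "k_act", "k_hyd", "k_rafact", "k_rafdeact", "k_fbraf", "k_recraf",
  "k_mekp", "k_mekdp", "k_fbmek", "k_recmek", "k_erkp", "k_erkdp", "km_erk",
  "k_dusp", "vmax_dusp", "k_half_dusp", "kdeg_dusp",
  "vmax_spry", "k_half_spry", "kdeg_spry", "k_spry", "hill_fb")

.param_total_names <- c("GS", "Ras", "RAF", "MEK", "ERK")

#' Validate a model parameter set
#'
#' Checks the structural invariants of a parameter list: strictly positive
#' protein totals, non-negative rate constants, and transcriptional
#' feedback (DUSP/SPRY) degradation half-lives of at least one hour, so
#' that transcriptional feedback is slower than the phosphorylation cycles.
#'
#' @param params a list with elements `totals` (named nM concentrations for
#'   `GS`, `Ras`, `RAF`, `MEK`, `ERK`) and `rates` (named per-hour or
#'   per-nM-per-hour rate constants; see [default_params()]).
#' @return `params`, invisibly, after validation.
#' @export
validate_params <- function(params) {
  if (!is.list(params) || is.null(params$totals) || is.null(params$rates))
    stop("`params` must be a list with `totals` and `rates` components")
  tot <- unlist(params$totals)
  miss <- setdiff(.param_total_names, names(tot))
  if (length(miss)) stop("missing totals: ", paste(miss, collapse = ", "))
  if (any(!is.finite(tot)) || any(tot[setdiff(.param_total_names, "GS")] <= 0))
    stop("protein totals must be strictly positive (GS may be zero)")
  if (tot["GS"] < 0) stop("GS total must be non-negative")
  r <- unlist(params$rates)
  miss <- setdiff(.param_rate_names, names(r))
  if (length(miss)) stop("missing rates: ", paste(miss, collapse = ", "))
  if (any(!is.finite(r)) || any(r < 0)) stop("rate constants must be non-negative")
  for (kd in c("kdeg_dusp", "kdeg_spry")) {
    if (r[kd] > log(2) + 1e-12)
      stop(kd, " implies a half-life < 1 h; transcriptional feedback must be ",
           "slower than the phosphorylation cycles")
  }
  invisible(params)
}

#' Default calibrated model parameters
#'
#' Reads the frozen default parameter file shipped with the package
#' (`inst/extdata/params_default.yaml`). Rate constants are adapted from
#' classic two-step distributive MAPK cascade models and calibrated (see
#' `scripts/calibrate.R` in the source tree and the package vignette) so
#' that the KRAS-coupled network reproduces the qualitative behavioral
#' constraints of chronically active MAPK signaling under MEK/ERK
#' inhibitor treatment: chronically elevated vehicle ppERK, pathway
#' reactivation under single-agent treatment by 24-72 h, CRAF activity
#' induction bands, and superiority of the half-dose combination.
#'
#' Units: concentrations nM, time h, first-order rates 1/h, second-order
#' rates 1/(nM h).
#'
#' @return A validated parameter list with components `totals`, `rates`,
#'   `inhibitors` (default MEK and ERK inhibitor binding parameters) and
#'   `link` (default viability link parameters).
#' @export
default_params <- function() {
  path <- system.file("extdata", "params_default.yaml", package = "mapkdual")
  if (path == "") stop("default parameter file not found")
  read_params(path)
}

#' Read / write model parameter files
#'
#' Parameter files are YAML with sections `totals`, `rates`, `feedbacks`
#' (optional), `inhibitors` (optional) and `link` (optional), all in the
#' units documented in [default_params()].
#'
#' @param path file path.
#' @return `read_params()` returns a validated parameter list;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  p <- yaml::read_yaml(path)
  validate_params(p)
  p
}

#' @rdname read_params
#' @param params a parameter list as returned by [default_params()].
#' @export
write_params <- function(params, path) {
  validate_params(params)
  yaml::write_yaml(params, path)
  invisible(path)
}

#' Default inhibitor specifications from a parameter list
#'
#' @param params a parameter list with an `inhibitors` section.
#' @return A list of two [inhibitor_spec()] objects (MEK, ERK).
#' @export
default_inhibitors <- function(params = default_params()) {
  inh <- params$inhibitors
  if (is.null(inh)) stop("parameter list has no `inhibitors` section")
  list(inhibitor_spec("MEK", inh$mek$kon, inh$mek$koff),
       inhibitor_spec("ERK", inh$erk$kon, inh$erk$koff))
}
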