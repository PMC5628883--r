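# Reaction-network assembly and steady-state machinery for the MAPK
# cascade model. Species (all nM):
#   RasGDP, RasGTP                         -- Ras nucleotide cycle
#   RAF, RAFa, RAFi                        -- inactive / active / feedback-
#                                             phosphorylated RAF
#   MEK, pMEK, MEKf (+ _D drug-bound)      -- MEK activation + feedback site
#   ERK, pERK, ppERK (+ _D drug-bound)     -- distributive double
#                                             phosphorylation of ERK
#   DUSP, SPRY                             -- transcriptional feedback species
# Free inhibitor concentrations are clamped (no depletion), so binding is
# first-order in the target with an effective rate kon * dose set at
# simulation time.

.mapk_species <- c(
  "RasGDP", "RasGTP",
  "RAF", "RAFa", "RAFi",
  "MEK", "pMEK", "MEKf", "MEK_D", "pMEK_D", "MEKf_D",
  "ERK", "pERK", "ppERK", "ERK_D", "pERK_D", "ppERK_D",
  "DUSP", "SPRY")

.mapk_moieties <- list(
  Ras = c("RasGDP", "RasGTP"),
  RAF = c("RAF", "RAFa", "RAFi"),
  MEK = c("MEK", "pMEK", "MEKf", "MEK_D", "pMEK_D", "MEKf_D"),
  ERK = c("ERK", "pERK", "ppERK", "ERK_D", "pERK_D", "ppERK_D"))

# One reaction: substrate (consumed), product (produced), optional
# mass-action modifier (catalyst, not consumed), base rate constant, tag.
.rxn <- function(name, k, sub = NA, prod = NA, mod = NA) {
  list(name = name, k = k, sub = sub, prod = prod, mod = mod)
}

.assemble_network <- function(params, config, inhibitors, k_rafconst = NA) {
  sp <- .mapk_species
  idx <- setNames(seq_along(sp), sp)
  r <- params$rates
  tot <- params$totals

  mek_inh <- Filter(function(i) i$target == "MEK", inhibitors)
  erk_inh <- Filter(function(i) i$target == "ERK", inhibitors)
  if (length(mek_inh) > 1L || length(erk_inh) > 1L)
    stop("at most one inhibitor per target")
  mek_inh <- if (length(mek_inh)) mek_inh[[1]] else NULL
  erk_inh <- if (length(erk_inh)) erk_inh[[1]] else NULL

  rx <- list()
  add <- function(...) rx[[length(rx) + 1L]] <<- .rxn(...)

  ## Ras nucleotide cycle (driven by Grb2-SOS; SPRY gates the input)
  add("ras_activation", r$k_act, "RasGDP", "RasGTP")   # scaled by GS_eff in rhs
  add("ras_hydrolysis", r$k_hyd, "RasGTP", "RasGDP")

  ## RAF activation
  if (config$ras_coupled) {
    add("raf_activation", r$k_rafact, "RAF", "RAFa", "RasGTP")
  } else {
    if (!is.finite(k_rafconst)) stop("decoupled network requires k_rafconst")
    add("raf_activation_constitutive", k_rafconst, "RAF", "RAFa")
  }
  add("raf_deactivation", r$k_rafdeact, "RAFa", "RAF")

  ## ppERK feedback phosphorylation of CRAF (RAS-coupled cycle only) and MEK
  if (config$fb_phospho && config$ras_coupled) {
    add("raf_feedback_phospho", r$k_fbraf, "RAFa", "RAFi", "ppERK")
    add("raf_feedback_recovery", r$k_recraf, "RAFi", "RAF")
  }
  if (config$fb_phospho) {
    add("mek_feedback_phospho", r$k_fbmek, "MEK", "MEKf", "ppERK")
    add("mek_feedback_recovery", r$k_recmek, "MEKf", "MEK")
    if (!is.null(mek_inh)) {
      add("mek_feedback_phospho_bound", r$k_fbmek, "MEK_D", "MEKf_D", "ppERK")
      add("mek_feedback_recovery_bound", r$k_recmek, "MEKf_D", "MEK_D")
    }
  }

  ## MEK activation by active RAF; bound MEK remains a substrate
  add("mek_phospho", r$k_mekp, "MEK", "pMEK", "RAFa")
  add("mek_dephospho", r$k_mekdp, "pMEK", "MEK")
  if (!is.null(mek_inh)) {
    add("mek_phospho_bound", r$k_mekp, "MEK_D", "pMEK_D", "RAFa")
    add("mek_dephospho_bound", r$k_mekdp, "pMEK_D", "MEK_D")
  }

  ## Distributive two-step ERK phosphorylation by free (unbound) pMEK
  erk_forms <- list(c("ERK", "pERK"), c("pERK", "ppERK"))
  for (f in erk_forms)
    add(paste0("erk_phospho_", f[1]), r$k_erkp, f[1], f[2], "pMEK")
  if (!is.null(erk_inh)) {
    for (f in erk_forms)
      add(paste0("erk_phospho_", f[1], "_bound"), r$k_erkp,
          paste0(f[1], "_D"), paste0(f[2], "_D"), "pMEK")
  }
  ## Basal ERK dephosphorylation
  dep <- list(c("pERK", "ERK"), c("ppERK", "pERK"))
  for (f in dep)
    add(paste0("erk_dephospho_", f[1]), r$k_erkdp, f[1], f[2])
  if (!is.null(erk_inh)) {
    for (f in dep)
      add(paste0("erk_dephospho_", f[1], "_bound"), r$k_erkdp,
          paste0(f[1], "_D"), paste0(f[2], "_D"))
  }

  ## DUSP feedback: ppERK-induced synthesis, DUSP-catalyzed dephosphorylation
  if (config$fb_dusp) {
    for (f in dep)
      add(paste0("dusp_dephospho_", f[1]), r$k_dusp, f[1], f[2], "DUSP")
    if (!is.null(erk_inh)) {
      for (f in dep)
        add(paste0("dusp_dephospho_", f[1], "_bound"), r$k_dusp,
            paste0(f[1], "_D"), paste0(f[2], "_D"), "DUSP")
    }
    add("dusp_synthesis", r$vmax_dusp, NA, "DUSP")   # Hill term in rhs
    add("dusp_degradation", r$kdeg_dusp, "DUSP", NA)
  }

  ## SPRY feedback: synthesis + degradation; inhibition of GS enters the
  ## Ras activation rate law (rhs), not a separate reaction.
  if (config$fb_spry) {
    add("spry_synthesis", r$vmax_spry, NA, "SPRY")   # Hill term in rhs
    add("spry_degradation", r$kdeg_spry, "SPRY", NA)
  }

  ## Reversible drug binding to every form of the target
  if (!is.null(mek_inh)) {
    for (f in c("MEK", "pMEK", "MEKf")) {
      add(paste0("bind_mek_", f), mek_inh$kon, f, paste0(f, "_D"))
      add(paste0("unbind_mek_", f), mek_inh$koff, paste0(f, "_D"), f)
    }
  }
  if (!is.null(erk_inh)) {
    for (f in c("ERK", "pERK", "ppERK")) {
      add(paste0("bind_erk_", f), erk_inh$kon, f, paste0(f, "_D"))
      add(paste0("unbind_erk_", f), erk_inh$koff, paste0(f, "_D"), f)
    }
  }

  nR <- length(rx)
  S <- matrix(0, nrow = length(sp), ncol = nR,
              dimnames = list(sp, vapply(rx, `[[`, "", "name")))
  k <- numeric(nR)
  i_sub <- integer(nR)   # 0 = no substrate (synthesis)
  i_mod <- integer(nR)   # 0 = no modifier
  for (j in seq_len(nR)) {
    rj <- rx[[j]]
    k[j] <- rj$k
    if (!is.na(rj$sub)) { S[idx[rj$sub], j] <- S[idx[rj$sub], j] - 1; i_sub[j] <- idx[rj$sub] }
    if (!is.na(rj$prod)) S[idx[rj$prod], j] <- S[idx[rj$prod], j] + 1
    i_mod[j] <- if (is.na(rj$mod)) 0L else idx[rj$mod]
  }
  nm <- colnames(S)
  mm_idx <- grep("^(erk|dusp)_dephospho_", nm)
  special <- list(
    ras = match("ras_activation", nm),
    dusp_syn = match("dusp_synthesis", nm),
    spry_syn = match("spry_synthesis", nm),
    bind_mek = grep("^bind_mek_", nm),
    bind_erk = grep("^bind_erk_", nm),
    mm = mm_idx,                      # saturable ERK dephosphorylation
    mm_sub = i_sub[mm_idx],
    mm_load = idx[c("pERK", "ppERK", "pERK_D", "ppERK_D")],
    spry_gates = isTRUE(config$fb_spry))

  init <- setNames(numeric(length(sp)), sp)
  init["RasGDP"] <- tot$Ras
  init["RAF"] <- tot$RAF
  init["MEK"] <- tot$MEK
  init["ERK"] <- tot$ERK

  structure(list(
    species = sp, idx = idx, S = S, k = k, i_sub = i_sub, i_mod = i_mod,
    special = special, params = params, config = config,
    inhibitors = list(mek = mek_inh, erk = erk_inh),
    moieties = .mapk_moieties, init = init,
    k_rafconst = k_rafconst), class = "reaction_network")
}

# Rate vector at state y for a network with (possibly dose-scaled) k.
.network_rates <- function(net, y, k) {
  yp <- pmax(y, 0)
  s1 <- ifelse(net$i_sub == 0L, 1, yp[pmax(net$i_sub, 1L)])
  s2 <- ifelse(net$i_mod == 0L, 1, yp[pmax(net$i_mod, 1L)])
  v <- k * s1 * s2
  r <- net$params$rates
  spc <- net$special
  gs_eff <- net$params$totals$GS
  if (spc$spry_gates) gs_eff <- gs_eff / (1 + yp[net$idx["SPRY"]] / r$k_spry)
  v[spc$ras] <- v[spc$ras] * gs_eff
  if (length(spc$mm)) {
    # competitive Michaelis-Menten: all phospho-ERK forms (free and
    # drug-bound) share one phosphatase pool
    load <- sum(yp[spc$mm_load])
    v[spc$mm] <- v[spc$mm] / (r$km_erk + load)
  }
  pp <- yp[net$idx["ppERK"]]
  if (!is.na(spc$dusp_syn)) {
    h <- pp^r$hill_fb
    v[spc$dusp_syn] <- v[spc$dusp_syn] * h / (r$k_half_dusp^r$hill_fb + h)
  }
  if (!is.na(spc$spry_syn)) {
    h <- pp^r$hill_fb
    v[spc$spry_syn] <- v[spc$spry_syn] * h / (r$k_half_spry^r$hill_fb + h)
  }
  v
}

.network_rhs <- function(net) {
  S <- net$S
  function(t, y, parms) {
    v <- .network_rates(net, y, parms$k)
    list(as.vector(S %*% v))
  }
}

# Dose-scaled rate-constant vector: binding reactions carry kon as base
# constant and are multiplied by the clamped free drug concentration.
.dosed_k <- function(net, dose_mek, dose_erk) {
  k <- net$k
  if (length(net$special$bind_mek)) k[net$special$bind_mek] <- k[net$special$bind_mek] * dose_mek
  if (length(net$special$bind_erk)) k[net$special$bind_erk] <- k[net$special$bind_erk] * dose_erk
  k
}

#' Build a MAPK cascade reaction network
#'
#' Assembles the mass-action reaction system for the RAS-RAF-MEK-ERK
#' cascade under a feedback configuration, registers inhibitor binding
#' reactions, and pre-equilibrates the drug-free (vehicle) steady state
#' that all simulations start from. Disabled feedbacks contribute no
#' reactions. With `ras_coupled = FALSE`, Ras-GTP-dependent RAF activation
#' is replaced by a constitutive first-order activation whose rate is sized
#' by root finding so that the vehicle steady-state pathway output matches
#' the corresponding RAS-coupled network, isolating the feedback-topology
#' difference from a baseline difference.
#'
#' @param params model parameters, see [default_params()].
#' @param config a [feedback_config()].
#' @param inhibitors a list of [inhibitor_spec()] objects, at most one per
#'   target. Defaults to the inhibitor parameters in `params` when present.
#' @return An object of class `reaction_network` with the stoichiometry
#'   matrix, rate table, cached vehicle steady state (`vehicle_ss`),
#'   vehicle pathway output (`vehicle_output`, free ppERK in nM) and
#'   vehicle active-RAF level (`vehicle_craf`).
#' @export
build_network <- function(params = default_params(),
                          config = feedback_config(),
                          inhibitors = NULL) {
  validate_params(params)
  if (!inherits(config, "feedback_config")) stop("`config` must be a feedback_config")
  if (is.null(inhibitors))
    inhibitors <- if (!is.null(params$inhibitors)) default_inhibitors(params) else list()
  targets <- vapply(inhibitors, `[[`, "", "target")
  if (anyDuplicated(targets)) stop("duplicate inhibitor target")

  k_rafconst <- NA_real_
  if (!config$ras_coupled) {
    coupled_cfg <- config
    coupled_cfg$ras_coupled <- TRUE
    coupled <- build_network(params, coupled_cfg, inhibitors)
    target_out <- coupled$vehicle_output
    out_at <- function(log10k) {
      net <- .assemble_network(params, config, inhibitors, 10^log10k)
      ss <- .solve_steady(net, .dosed_k(net, 0, 0), net$init)
      ss$state[net$idx["ppERK"]]
    }
    f <- function(lk) out_at(lk) - target_out
    lo <- -6; hi <- 2
    while (f(hi) < 0 && hi < 6) hi <- hi + 1
    while (f(lo) > 0 && lo > -10) lo <- lo - 1
    k_rafconst <- 10^uniroot(f, c(lo, hi), tol = 1e-10)$root
  }

  net <- .assemble_network(params, config, inhibitors, k_rafconst)
  ss <- .solve_steady(net, .dosed_k(net, 0, 0), net$init)
  if (!ss$converged)
    warning("vehicle steady state did not converge within the time horizon")
  net$vehicle_ss <- setNames(ss$state, net$species)
  net$vehicle_output <- unname(ss$state[net$idx["ppERK"]])
  net$vehicle_craf <- unname(ss$state[net$idx["RAFa"]])
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cfg <- x$config
  cat("MAPK cascade reaction network\n")
  cat(sprintf("  species: %d, reactions: %d\n", length(x$species), ncol(x$S)))
  cat(sprintf("  ras_coupled: %s  fb_phospho: %s  fb_dusp: %s  fb_spry: %s\n",
              cfg$ras_coupled, cfg$fb_phospho, cfg$fb_dusp, cfg$fb_spry))
  inh <- Filter(Negate(is.null), x$inhibitors)
  for (i in inh)
    cat(sprintf("  %s inhibitor: Kd = %.3g nM\n", i$target, i$kd))
  cat(sprintf("  vehicle ppERK: %.3g nM (%.1f%% of total ERK)\n",
              x$vehicle_output, 100 * x$vehicle_output / x$params$totals$ERK))
  invisible(x)
}

# Integrate to steady state: chunked stiff integration until the maximum
# relative rate of change falls below `tol` per hour, or t_max is reached.
.solve_steady <- function(net, k, y0, tol = 1e-8, t_max = 1000, chunk = 50) {
  rhs <- .network_rhs(net)
  parms <- list(k = k)
  y <- y0
  t <- 0
  repeat {
    sol <- deSolve::lsoda(y, times = c(0, chunk / 2, chunk), func = rhs,
                          parms = parms, rtol = 1e-8, atol = 1e-10,
                          maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0)
      stop("steady-state integration failed at t = ", t, " h")
    y <- sol[nrow(sol), -1]
    t <- t + chunk
    dy <- rhs(0, y, parms)[[1]]
    rel <- max(abs(dy) / (abs(y) + 1e-10))
    if (rel < tol) return(list(state = unname(y), converged = TRUE, t = t, rel_rate = rel))
    if (t >= t_max) return(list(state = unname(y), converged = FALSE, t = t, rel_rate = rel))
  }
}

#' Steady state of the network under clamped inhibitor doses
#'
#' Integrates the system until the maximum relative rate of change is below
#' `1e-8`/h (or 1000 h is reached, in which case the result is flagged as
#' non-converged rather than failing silently). The integration starts from
#' the pre-equilibrated vehicle steady state unless `init` is supplied.
#'
#' @param network a [build_network()] object.
#' @param dose_mek,dose_erk clamped free inhibitor concentrations (nM).
#' @param init optional initial state (named nM vector).
#' @return A list with `state` (named nM vector), `output` (free ppERK,
#'   nM), `converged` flag and the time integrated.
#' @export
steady_state <- function(network, dose_mek = 0, dose_erk = 0, init = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  if (dose_mek < 0 || dose_erk < 0) stop("doses must be non-negative")
  y0 <- init %||% network$vehicle_ss
  k <- .dosed_k(network, dose_mek, dose_erk)
  ss <- .solve_steady(network, k, y0)
  list(state = setNames(ss$state, network$species),
       output = unname(ss$state[network$idx["ppERK"]]),
       converged = ss$converged, t = ss$t, rel_rate = ss$rel_rate)
}
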