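# Synthetic-data generators. Every generator is a pure function of its
# spec (seed included): the seed is part of the spec and is restored into
# the RNG locally, so repeated calls reproduce the same draw. Each
# generated object carries a machine-readable `truth` attribute consumed by
# parameter-recovery tests.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default single-agent screening dose ladder
#'
#' Eight concentrations from 50 uM in decreasing 3-fold dilutions, in nM.
#'
#' @return Numeric dose vector, length 8 (nM, increasing).
#' @export
screening_doses <- function() sort(50000 / 3^(0:7))

#' Generate noisy single-agent dose-response curves
#'
#' Samples replicate effect tables from a true 4PL at the stated doses with
#' additive Gaussian noise, clipped to the effect scale.
#'
#' @param n_curves number of independent curves.
#' @param doses dose ladder (nM); default [screening_doses()].
#' @param top,bottom,ec50,hill true 4PL parameters. `ec50` may be a vector
#'   of length `n_curves` (recycled otherwise); effects are percent scale.
#' @param sd Gaussian noise standard deviation (percent-effect units).
#' @param replicates technical replicates per dose.
#' @param seed RNG seed (recorded in the truth metadata).
#' @return A data frame with `curve`, `replicate`, `dose`, `effect`, with a
#'   `truth` attribute (data frame of the generating parameters plus the
#'   seed and noise sd).
#' @export
gen_curves <- function(n_curves = 1, doses = screening_doses(),
                       top = 100, bottom = 0, ec50 = 100, hill = 1,
                       sd = 0, replicates = 1, seed = 1) {
  if (length(doses) < 2 || any(doses < 0) || any(diff(sort(doses)) == 0))
    stop("degenerate dose layout")
  if (sd < 0) stop("`sd` must be non-negative")
  ec50 <- rep_len(ec50, n_curves)
  top <- rep_len(top, n_curves); bottom <- rep_len(bottom, n_curves)
  hill <- rep_len(hill, n_curves)
  .with_seed(seed, {
    rows <- lapply(seq_len(n_curves), function(i) {
      true_eff <- fourpl(rep(doses, replicates), top[i], bottom[i],
                         ec50[i], hill[i])
      eff <- true_eff + rnorm(length(true_eff), 0, sd)
      eff <- pmin(pmax(eff, min(bottom[i], 0)), max(top[i], 100))
      data.frame(curve = i, replicate = rep(seq_len(replicates),
                                            each = length(doses)),
                 dose = rep(doses, replicates), effect = eff)
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- data.frame(curve = seq_len(n_curves), top = top,
                                     bottom = bottom, ec50 = ec50,
                                     hill = hill, sd = sd, seed = seed)
    out
  })
}

#' Generate a two-drug combination matrix under a known interaction null
#'
#' Synthesizes an observed effect matrix as the expectation under a named
#' null (Loewe additivity, computed with the same root-finding solver used
#' by the analysis; Bliss independence in closed form; or a sham
#' self-combination of drug A, where the cell at doses (dA, dB) is the
#' single-agent effect at dA + dB), plus an optional localized synergy bump
#' and Gaussian noise, clipped to \[0, 1\].
#'
#' @param doses_a,doses_b dose axes (nM).
#' @param curve_a,curve_b fraction-scale [dose_response_curve()]s of the
#'   two agents (for `null = "sham"` only `curve_a` is used).
#' @param null `"loewe"`, `"bliss"` or `"sham"`.
#' @param bump_amplitude synergy bump height (fraction effect) added over
#'   the bump region.
#' @param bump_region function of (dose_a, dose_b) returning the bump
#'   weight in \[0, 1\]; default a raised window over the middle third of
#'   each log-dose axis.
#' @param sd Gaussian noise sd on the fraction-effect scale.
#' @param seed RNG seed.
#' @return A [dose_grid()] (provenance `"synthetic"`) with a `truth`
#'   attribute recording the null, curves, bump mass and seed.
#' @export
gen_matrix <- function(doses_a = default_dose_grid(),
                       doses_b = default_dose_grid(),
                       curve_a = dose_response_curve(1, 0, 10, 1),
                       curve_b = dose_response_curve(1, 0, 30, 1),
                       null = c("loewe", "bliss", "sham"),
                       bump_amplitude = 0, bump_region = NULL,
                       sd = 0, seed = 1) {
  null <- match.arg(null)
  if (sd < 0) stop("`sd` must be non-negative")
  na <- length(doses_a); nb <- length(doses_b)
  base <- matrix(NA_real_, na, nb)
  if (null == "bliss") {
    base <- outer(predict(curve_a, doses_a), predict(curve_b, doses_b),
                  bliss_expected)
  } else if (null == "sham") {
    base <- matrix(predict(curve_a, outer(doses_a, doses_b, `+`)), na, nb)
    curve_b <- curve_a
  } else {
    for (i in seq_len(na)) for (j in seq_len(nb))
      base[i, j] <- loewe_expected(curve_a, curve_b, doses_a[i], doses_b[j])
  }
  bump <- matrix(0, na, nb)
  if (bump_amplitude != 0) {
    if (is.null(bump_region)) {
      mid_w <- function(d) {
        ld <- log10(pmax(d, min(d[d > 0]) / 10))
        lo <- quantile(ld, 1 / 3); hi <- quantile(ld, 2 / 3)
        as.numeric(ld >= lo & ld <= hi)
      }
      bump <- outer(mid_w(doses_a), mid_w(doses_b))
    } else {
      bump <- outer(doses_a, doses_b, Vectorize(bump_region))
    }
    bump <- bump_amplitude * bump
    if (max(base + bump) > 1.2)
      warning("synergy bump drives expected effects above 1 by more than 0.2 before clipping")
  }
  eff <- .with_seed(seed, base + bump + matrix(rnorm(na * nb, 0, sd), na, nb))
  eff <- pmin(pmax(eff, 0), 1)
  g <- dose_grid(doses_a, doses_b, eff, provenance = "synthetic")
  attr(g, "truth") <- list(null = null, curve_a = curve_a, curve_b = curve_b,
                           bump_amplitude = bump_amplitude,
                           bump_mass = sum(bump), n_cells = na * nb,
                           sd = sd, seed = seed)
  g
}

#' Generate a synthetic xenograft cohort
#'
#' Per-animal exponential tumor growth on the log2 scale with animal-level
#' slope jitter and measurement-level lognormal (scale-proportional
#' caliper) noise, on a twice-weekly measurement schedule. An optional
#' exponential death process can mark deaths before study end.
#'
#' @param groups named numeric vector of group growth slopes (log2
#'   units/day); names are group labels. A doubling time of `d` days is a
#'   slope of `1/d`.
#' @param n animals per group.
#' @param baseline mean baseline volume (mm3) at day 0.
#' @param days measurement schedule (days); default twice weekly for 21 d.
#' @param slope_jitter_sd between-animal sd of the growth slope.
#' @param noise_sd sd of the lognormal measurement noise (log2 scale).
#' @param death_rate per-day hazard of on-study death (0 = none).
#' @param seed RNG seed.
#' @return A [tumor_cohort()] with a `death_day` column and a `truth`
#'   attribute (per-animal true slopes, group slopes, doubling times, seed).
#' @export
gen_cohort <- function(groups = c(vehicle = 0.2, treated = 0.05), n = 10,
                       baseline = 150, days = seq(0, 21, by = 3.5),
                       slope_jitter_sd = 0, noise_sd = 0,
                       death_rate = 0, seed = 1) {
  if (any(!is.finite(groups))) stop("group slopes must be finite")
  if (is.null(names(groups))) stop("`groups` must be a named vector")
  if (n < 1 || noise_sd < 0 || slope_jitter_sd < 0 || death_rate < 0)
    stop("invalid cohort spec")
  .with_seed(seed, {
    rows <- list(); truth_rows <- list()
    for (g in names(groups)) for (i in seq_len(n)) {
      id <- paste0(g, "_", i)
      slope <- groups[[g]] + rnorm(1, 0, slope_jitter_sd)
      death <- if (death_rate > 0) stats::rexp(1, death_rate) else Inf
      death_day <- if (death <= max(days)) death else NA_real_
      obs_days <- if (is.na(death_day)) days else days[days <= death_day]
      if (length(obs_days) < 1) obs_days <- days[1]
      l2v <- log2(baseline) + slope * obs_days +
        rnorm(length(obs_days), 0, noise_sd)
      rows[[id]] <- data.frame(animal = id, group = g, day = obs_days,
                               volume = 2^l2v, death_day = death_day)
      truth_rows[[id]] <- data.frame(animal = id, group = g,
                                     true_slope = slope,
                                     doubling_days = 1 / slope)
    }
    cohort <- tumor_cohort(do.call(rbind, rows))
    rownames(cohort) <- NULL
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    attr(cohort, "truth") <- list(animals = truth, group_slopes = groups,
                                  baseline = baseline, noise_sd = noise_sd,
                                  slope_jitter_sd = slope_jitter_sd,
                                  seed = seed)
    cohort
  })
}
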