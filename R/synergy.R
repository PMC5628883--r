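# Combination-synergy analysis: Loewe additivity and Bliss independence
# expectation surfaces, excess matrices and scalar synergy scores.
# Throughout this module effects are "fraction affected" (0-1, i.e.
# 1 - fractional viability); conversion from percent curves is explicit
# via effect_as_fraction().

#' Dose grid (two-drug response matrix)
#'
#' Container for a two-drug combination experiment: dose axes in nM and a
#' matrix of fractional effects in \[0, 1\] (rows index drug A doses,
#' columns drug B doses). Dose vectors must be strictly increasing, with an
#' optional leading zero.
#'
#' @param doses_a,doses_b dose vectors (nM).
#' @param effects matrix of fractional effects, `length(doses_a)` by
#'   `length(doses_b)`.
#' @param provenance one of `"simulated"`, `"measured"`, `"synthetic"`.
#' @param drug_a,drug_b optional drug labels.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(doses_a, doses_b, effects,
                      provenance = c("simulated", "measured", "synthetic"),
                      drug_a = "A", drug_b = "B") {
  provenance <- match.arg(provenance)
  if (!is.matrix(effects) || nrow(effects) != length(doses_a) ||
      ncol(effects) != length(doses_b))
    stop("`effects` dimensions must match the dose axes")
  for (d in list(doses_a, doses_b)) {
    if (any(d < 0)) stop("doses must be non-negative")
    if (any(diff(d) <= 0)) stop("dose vectors must be strictly increasing")
  }
  if (any(effects < -1e-9 | effects > 1 + 1e-9))
    stop("effects must be fractions in [0, 1]")
  effects <- pmin(pmax(effects, 0), 1)
  structure(list(doses_a = doses_a, doses_b = doses_b, effects = effects,
                 provenance = provenance, drug_a = drug_a, drug_b = drug_b),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose_grid (%s): %d x %d, %s (%g-%g nM) x %s (%g-%g nM)\n",
              x$provenance, length(x$doses_a), length(x$doses_b),
              x$drug_a, min(x$doses_a), max(x$doses_a),
              x$drug_b, min(x$doses_b), max(x$doses_b)))
  invisible(x)
}

#' Default nine-dose half-log grid
#'
#' Nine half-log-spaced doses spanning 0.1-1000 nM (exponents -1 to 3).
#' A "1 to 1000 nM in half-log dilution steps" layout yields only seven
#' values, so a nine-point matrix cannot use those endpoints exactly; this
#' grid keeps the half-log spacing and nine points by extending one
#' half-log step below 1 nM and anchoring the top at 1000 nM. An
#' alternative layout of eight half-log steps from 1000 nM down plus a
#' zero dose is available via `zero_anchored = TRUE`.
#'
#' @param zero_anchored use the alternative 0 + eight half-log doses layout.
#' @return Numeric dose vector (nM), length 9.
#' @export
default_dose_grid <- function(zero_anchored = FALSE) {
  if (zero_anchored) c(0, 10^seq(-0.5, 3, by = 0.5))
  else 10^seq(-1, 3, by = 0.5)
}

#' Bliss independence expectation
#'
#' Probabilistic null for two independently acting agents:
#' `E = eA + eB - eA * eB`.
#'
#' @param e_a,e_b single-agent fractional effects in \[0, 1\] (vectorized).
#' @return Expected fractional combination effect.
#' @export
bliss_expected <- function(e_a, e_b) {
  if (any(e_a < 0 | e_a > 1 | e_b < 0 | e_b > 1, na.rm = TRUE))
    stop("effects must be fractions in [0, 1]")
  e_a + e_b - e_a * e_b
}

#' Invert a 4PL curve at an effect level
#'
#' The dose-equivalence term D(E) of the Loewe equation: the unique dose at
#' which the curve reaches fractional effect `effect`, by analytic 4PL
#' inversion. Levels at or above the top asymptote return an infinite-dose
#' sentinel (`Inf`, with attribute `saturated = TRUE`); levels at or below
#' the bottom return 0.
#'
#' @param curve a [dose_response_curve()] (fraction scale for synergy use).
#' @param effect effect level, same scale as the curve.
#' @return Dose in nM (possibly `0` or `Inf`).
#' @export
invert_curve <- function(curve, effect) {
  stopifnot(inherits(curve, "drc_4pl"))
  if (curve$top <= curve$bottom) stop("curve is degenerate (top == bottom)")
  out <- numeric(length(effect))
  hi <- effect >= curve$top
  lo <- effect <= curve$bottom
  mid <- !hi & !lo
  f <- (effect[mid] - curve$bottom) / (curve$top - effect[mid])
  out[mid] <- curve$ec50 * f^(1 / curve$hill)
  out[hi] <- Inf
  out[lo] <- 0
  if (any(hi)) attr(out, "saturated") <- TRUE
  out
}

#' Loewe-additive expected effect of a dose pair
#'
#' Solves the Loewe dose-equivalence equation
#' `dA / D_A(E) + dB / D_B(E) = 1` for the expected fractional effect `E`
#' by bracketed monotone root finding on
#' `E` in `(max(bottoms), min(tops))`. When one dose is zero the other
#' curve's effect is returned exactly. When no root exists below the shared
#' effect ceiling (both doses beyond what either agent can be credited
#' for), the ceiling `min(topA, topB)` is returned with attribute
#' `saturated = TRUE` rather than extrapolating.
#'
#' @param curve_a,curve_b monotone 4PL single-agent curves (fraction scale).
#' @param dose_a,dose_b doses in nM (scalars, non-negative).
#' @param tol root-finding tolerance on E.
#' @return Expected fractional effect (scalar).
#' @export
loewe_expected <- function(curve_a, curve_b, dose_a, dose_b, tol = 1e-12) {
  stopifnot(inherits(curve_a, "drc_4pl"), inherits(curve_b, "drc_4pl"))
  if (dose_a < 0 || dose_b < 0) stop("doses must be non-negative")
  if (curve_a$top <= curve_a$bottom || curve_b$top <= curve_b$bottom)
    stop("curves must be strictly monotone (top > bottom)")
  if (dose_a == 0 && dose_b == 0)
    return(max(curve_a$bottom, curve_b$bottom))
  if (dose_b == 0) return(predict(curve_a, dose_a))
  if (dose_a == 0) return(predict(curve_b, dose_b))
  lo <- max(curve_a$bottom, curve_b$bottom)
  hi <- min(curve_a$top, curve_b$top)
  if (hi <= lo) stop("curves have no overlapping effect range")
  f <- function(e)
    dose_a / invert_curve(curve_a, e) + dose_b / invert_curve(curve_b, e) - 1
  eps <- (hi - lo) * 1e-13
  e_hi <- hi - eps
  if (f(e_hi) >= 0) return(structure(hi, saturated = TRUE))
  # f decreases in e and f -> +Inf as e -> lo+ (some D(e) -> 0); expand the
  # lower end past any non-finite region, and treat f(lo+) <= 0 (doses
  # negligible against both curves) as expected effect at the shared floor.
  e_lo <- lo + eps
  while (!is.finite(f(e_lo)) && e_lo < e_hi) e_lo <- lo + (e_lo - lo) * 10
  if (f(e_lo) <= 0) return(lo)
  unname(uniroot(f, c(e_lo, e_hi), tol = tol)$root)
}

#' Build a synergy surface from a dose grid
#'
#' Computes the expected effect matrix under a named interaction null
#' (Loewe additivity via [loewe_expected()], or Bliss independence), the
#' excess matrix `observed - expected`, and the scalar synergy score.
#' Single-agent curves can be supplied; otherwise they are fitted by
#' [fit_4pl()] to the grid's zero-dose margins (which then must be
#' present). Supplied curves whose margin predictions disagree with the
#' grid's observed zero-dose margins beyond `margin_tol` trigger a warning
#' and a refit from the margins.
#'
#' @param grid a [dose_grid()] of fractional effects.
#' @param curve_a,curve_b optional fraction-scale [dose_response_curve()]s
#'   for the two single agents.
#' @param null_model `"loewe"` or `"bliss"`.
#' @param weighting synergy-score weighting, see [synergy_score()].
#' @param margin_tol maximum tolerated mean absolute margin mismatch.
#' @return An object of class `synergy_surface` with `observed`,
#'   `expected`, `excess` matrices, dose axes, the curves used, the null
#'   tag, and `score`.
#' @export
build_surface <- function(grid, curve_a = NULL, curve_b = NULL,
                          null_model = c("loewe", "bliss"),
                          weighting = c("uniform", "effect_weighted"),
                          margin_tol = 0.05) {
  stopifnot(inherits(grid, "dose_grid"))
  null_model <- match.arg(null_model)
  weighting <- match.arg(weighting)
  da <- grid$doses_a; db <- grid$doses_b
  obs <- grid$effects

  refit_a <- function() {
    if (db[1] != 0) stop("no curve for drug A and no zero-dose margin to fit")
    fit_4pl(da, obs[, 1])
  }
  refit_b <- function() {
    if (da[1] != 0) stop("no curve for drug B and no zero-dose margin to fit")
    fit_4pl(db, obs[1, ])
  }
  if (is.null(curve_a)) curve_a <- refit_a()
  else if (db[1] == 0) {
    mm <- mean(abs(predict(curve_a, da) - obs[, 1]))
    if (mm > margin_tol) {
      warning(sprintf("drug A margin/curve mismatch (mean %.3g); refitting", mm))
      curve_a <- refit_a()
    }
  }
  if (is.null(curve_b)) curve_b <- refit_b()
  else if (da[1] == 0) {
    mm <- mean(abs(predict(curve_b, db) - obs[1, ]))
    if (mm > margin_tol) {
      warning(sprintf("drug B margin/curve mismatch (mean %.3g); refitting", mm))
      curve_b <- refit_b()
    }
  }

  expected <- matrix(NA_real_, nrow(obs), ncol(obs))
  if (null_model == "bliss") {
    ea <- pmin(pmax(predict(curve_a, da), 0), 1)
    eb <- pmin(pmax(predict(curve_b, db), 0), 1)
    expected <- outer(ea, eb, bliss_expected)
  } else {
    for (i in seq_along(da)) for (j in seq_along(db))
      expected[i, j] <- loewe_expected(curve_a, curve_b, da[i], db[j])
  }
  expected <- pmin(pmax(expected, 0), 1)
  surface <- structure(list(
    observed = obs, expected = expected, excess = obs - expected,
    doses_a = da, doses_b = db, null_model = null_model,
    curve_a = curve_a, curve_b = curve_b,
    drug_a = grid$drug_a, drug_b = grid$drug_b,
    weighting = weighting, provenance = grid$provenance),
    class = "synergy_surface")
  surface$score <- synergy_score(surface, weighting)
  surface
}

#' @export
print.synergy_surface <- function(x, ...) {
  cat(sprintf("synergy_surface: %s null, %d x %d grid\n",
              x$null_model, nrow(x$observed), ncol(x$observed)))
  cat(sprintf("  score (%s): %.4g   max excess: %.4g   min excess: %.4g\n",
              x$weighting, x$score, max(x$excess), min(x$excess)))
  invisible(x)
}

#' Scalar synergy score of a surface
#'
#' A weighted sum of the values in excess of the expected (null-model)
#' effects, scaled by 100. `"uniform"` weighting is the mean excess times
#' 100; `"effect_weighted"` weights each cell's excess by its expected
#' effect (down-weighting the flat low-dose corner) and normalizes by the
#' mean weight. Positive and negative excess both contribute; scores are
#' comparable only within one weighting scheme.
#'
#' @param surface a [build_surface()] result.
#' @param weighting `"uniform"` or `"effect_weighted"`.
#' @return Scalar score.
#' @export
synergy_score <- function(surface,
                          weighting = c("uniform", "effect_weighted")) {
  stopifnot(inherits(surface, "synergy_surface"))
  weighting <- match.arg(weighting)
  ex <- surface$excess
  if (weighting == "uniform") return(100 * mean(ex))
  w <- surface$expected
  if (sum(w) <= 0) return(0)
  100 * sum(ex * w) / sum(w)
}
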