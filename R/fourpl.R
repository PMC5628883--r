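#' Four-parameter logistic (4PL) dose-response function
#'
#' Effect increases with dose from `bottom` to `top`:
#' `effect(d) = bottom + (top - bottom) * d^hill / (d^hill + ec50^hill)`.
#' Effects may be expressed as percent (0-100, the fitting/GI50 convention)
#' or fraction affected (0-1, the synergy-surface convention); the
#' parameters simply share whichever scale the data use.
#'
#' @param dose dose vector (nM), non-negative.
#' @param top,bottom upper and lower asymptotes (`bottom <= top`).
#' @param ec50 dose of half-maximal effect (nM, > 0).
#' @param hill Hill slope (> 0).
#' @return Effect at each dose.
#' @export
fourpl <- function(dose, top, bottom, ec50, hill) {
  out <- numeric(length(dose))
  inf_d <- is.infinite(dose)
  dh <- dose[!inf_d]^hill
  out[!inf_d] <- bottom + (top - bottom) * dh / (dh + ec50^hill)
  out[inf_d] <- top
  out
}

#' Construct a 4PL dose-response curve object
#'
#' @inheritParams fourpl
#' @param diagnostics optional fit diagnostics (attached by [fit_4pl()]).
#' @return An object of class `drc_4pl`.
#' @export
dose_response_curve <- function(top, bottom, ec50, hill, diagnostics = NULL) {
  if (!all(is.finite(c(top, bottom, ec50, hill))))
    stop("curve parameters must be finite")
  if (bottom > top) stop("`bottom` must not exceed `top`")
  if (ec50 <= 0) stop("`ec50` must be positive")
  if (hill <= 0) stop("`hill` must be positive")
  structure(list(top = top, bottom = bottom, ec50 = ec50, hill = hill,
                 diagnostics = diagnostics), class = "drc_4pl")
}

#' @export
predict.drc_4pl <- function(object, dose, ...) {
  fourpl(dose, object$top, object$bottom, object$ec50, object$hill)
}

#' @export
print.drc_4pl <- function(x, ...) {
  cat(sprintf("4PL curve: top %.4g, bottom %.4g, EC50 %.4g nM, hill %.3g\n",
              x$top, x$bottom, x$ec50, x$hill))
  if (!is.null(x$diagnostics)) {
    d <- x$diagnostics
    cat(sprintf("  fit: converged %s, residual scale %.3g, %d outlier(s)\n",
                d$converged, d$sigma, sum(d$outlier)))
  }
  invisible(x)
}

# Tukey bisquare weights at standardized residual u (c = 4.685).
.bisquare_w <- function(u, cc = 4.685) {
  w <- (1 - (u / cc)^2)^2
  w[abs(u) >= cc] <- 0
  w
}

.fit_4pl_grid <- function(dose, effect, w, top_bounds) {
  # Fallback/starting estimate: profile top/bottom linearly over an
  # (ec50, hill) grid.
  lec_grid <- seq(log10(min(dose[dose > 0])) - 0.5,
                  log10(max(dose)) + 0.5, length.out = 40)
  hill_grid <- c(0.5, 0.75, 1, 1.5, 2, 3)
  best <- NULL
  for (h in hill_grid) for (lec in lec_grid) {
    f <- dose^h / (dose^h + (10^lec)^h)
    X <- cbind(1, f)
    fit <- stats::lm.wfit(X, effect, w)
    bottom <- fit$coefficients[1]
    top <- bottom + fit$coefficients[2]
    if (!is.finite(top) || !is.finite(bottom) || top < bottom) next
    if (!is.null(top_bounds)) top <- min(max(top, top_bounds[1]), top_bounds[2])
    pred <- bottom + (top - bottom) * f
    rss <- sum(w * (effect - pred)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(top = top, bottom = bottom, ec50 = 10^lec, hill = h, rss = rss)
  }
  best
}

#' Fit a 4PL curve with robust outlier down-weighting
#'
#' Iteratively reweighted Levenberg-Marquardt fit of the four-parameter
#' logistic, using Tukey bisquare weights (c = 4.685, three reweighting
#' iterations) followed by a leave-one-out refit that resolves the case of
#' a single gross outlier bracketed by clean points (where reweighting
#' alone settles into a compromise). In
#' screening mode the infinite-dose asymptote can be constrained, mirroring
#' screening pipelines that allow the lower viability asymptote to vary
#' between 50 and 100% effect (`lower_asymptote_bounds = c(50, 100)` with
#' percent effects).
#'
#' @param dose dose vector (nM); at least 5 points spanning at least two
#'   log10 units (zero doses are allowed and anchor the bottom asymptote).
#' @param effect observed effects (same length; percent 0-100 or fraction
#'   0-1 scale, used consistently).
#' @param lower_asymptote_bounds optional length-2 bounds for the
#'   infinite-dose effect asymptote (`top`), in the effect units used.
#' @param robust logical; apply bisquare reweighting (default `TRUE`).
#' @return A [dose_response_curve()] with a `diagnostics` list: `sigma`
#'   (robust residual scale), `weights`, `outlier` mask (final bisquare
#'   weight below 0.2), `converged` flag and `method`.
#' @export
fit_4pl <- function(dose, effect, lower_asymptote_bounds = NULL,
                    robust = TRUE) {
  if (length(dose) != length(effect)) stop("`dose` and `effect` lengths differ")
  keep <- is.finite(dose) & is.finite(effect) & dose >= 0
  dose <- dose[keep]; effect <- effect[keep]
  if (length(dose) < 5) stop("need at least 5 dose points")
  pos <- dose > 0
  if (log10(max(dose[pos]) / min(dose[pos])) < 2)
    stop("doses must span at least two log10 units")
  if (diff(range(effect)) < .Machine$double.eps^0.25 * max(1, abs(mean(effect))))
    stop("degenerate (flat) response data; no curve can be identified")
  tb <- lower_asymptote_bounds
  if (!is.null(tb)) { stopifnot(length(tb) == 2); tb <- sort(tb) }

  w <- rep(1, length(dose))
  span <- diff(range(effect))
  lower <- c(top = min(effect) , bottom = min(effect) - 0.1 * span,
             lec = log10(min(dose[pos])) - 2, hill = 0.1)
  upper <- c(top = max(effect) + 0.5 * span, bottom = max(effect),
             lec = log10(max(dose)) + 2, hill = 8)
  if (!is.null(tb)) { lower["top"] <- tb[1]; upper["top"] <- tb[2] }

  start <- .fit_4pl_grid(dose, effect, w, tb)
  st <- c(top = min(max(start$top, lower["top"]), upper["top"]),
          bottom = min(max(start$bottom, lower["bottom"]), upper["bottom"]),
          lec = log10(start$ec50), hill = start$hill)
  names(st) <- c("top", "bottom", "lec", "hill")
  # nudge off the exact grid optimum: a start coinciding with a finite-
  # difference lattice point can yield a numerically singular gradient
  st["lec"] <- st["lec"] + 1e-6
  st["hill"] <- st["hill"] * (1 + 1e-6)

  converged <- FALSE
  pars <- st
  n_iter <- if (robust) 3L else 1L
  df <- data.frame(dose = dose, effect = effect)
  for (it in seq_len(n_iter)) {
    fit <- tryCatch(
      do.call(minpack.lm::nlsLM, list(
        effect ~ bottom + (top - bottom) * dose^hill / (dose^hill + (10^lec)^hill),
        data = df, start = as.list(pars), weights = w,
        lower = unname(lower), upper = unname(upper),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) break
    pars <- coef(fit)
    converged <- TRUE
    if (!robust) break
    res <- effect - (pars["bottom"] + (pars["top"] - pars["bottom"]) *
                       dose^pars["hill"] / (dose^pars["hill"] + (10^pars["lec"])^pars["hill"]))
    s <- stats::mad(res, center = 0)
    if (s < 1e-9 * max(1, span)) break
    w_new <- .bisquare_w(res / s)
    if (max(abs(w_new - w)) < 1e-3) { w <- w_new; break }
    w <- w_new
  }

  pred4 <- function(p) p["bottom"] + (p["top"] - p["bottom"]) *
    dose^p["hill"] / (dose^p["hill"] + (10^p["lec"])^p["hill"])

  # A single gross outlier bracketed by clean points can trap the
  # reweighted fit in a compromise where two residuals share the blame;
  # a leave-one-out refit resolves the ambiguity decisively.
  if (robust && converged) {
    res <- effect - pred4(pars)
    cand <- order(-abs(res))[seq_len(min(3, length(dose) - 5))]
    cand <- cand[abs(res[cand]) > 0.04 * span]
    for (i in cand) {
      w_i <- w; w_i[i] <- 0
      g_i <- .fit_4pl_grid(dose, effect, w_i, tb)
      st_i <- list(top = min(max(g_i$top, lower[["top"]]), upper[["top"]]),
                   bottom = min(max(g_i$bottom, lower[["bottom"]]), upper[["bottom"]]),
                   lec = log10(g_i$ec50) + 1e-6,
                   hill = g_i$hill * (1 + 1e-6))
      fit_i <- tryCatch(
        do.call(minpack.lm::nlsLM, list(
          effect ~ bottom + (top - bottom) * dose^hill / (dose^hill + (10^lec)^hill),
          data = df, start = st_i, weights = w_i,
          lower = unname(lower), upper = unname(upper),
          control = minpack.lm::nls.lm.control(maxiter = 200))),
        error = function(e) NULL)
      if (is.null(fit_i)) next
      p_i <- coef(fit_i)
      res_i <- effect - pred4(p_i)
      keep <- seq_along(dose) != i
      if (mean(res_i[keep]^2) < 0.25 * mean(res[keep]^2)) {
        pars <- p_i
        w <- w_i
        break
      }
    }
  }

  if (!converged) {                      # grid-search fallback, flagged
    g <- .fit_4pl_grid(dose, effect, rep(1, length(dose)), tb)
    pars <- c(top = g$top, bottom = g$bottom, lec = log10(g$ec50), hill = g$hill)
  }
  pred <- pars["bottom"] + (pars["top"] - pars["bottom"]) *
    dose^pars["hill"] / (dose^pars["hill"] + (10^pars["lec"])^pars["hill"])
  res <- effect - pred
  sigma <- stats::mad(res, center = 0)
  dose_response_curve(
    top = unname(pars["top"]), bottom = unname(min(pars["bottom"], pars["top"])),
    ec50 = unname(10^pars["lec"]), hill = unname(pars["hill"]),
    diagnostics = list(sigma = sigma, weights = w, outlier = w < 0.2,
                       residuals = res, converged = converged,
                       method = if (converged) "IRLS-LM" else "grid fallback",
                       lower_asymptote_bounds = tb))
}

#' GI50: dose producing 50% effect
#'
#' Analytic inversion of a fitted 4PL at the 50% effect level (percent
#' scale by default; pass `level = 0.5` for fraction-scale curves). When
#' the curve's asymptotes do not straddle the level, the value is censored
#' and reported relative to the maximum tested dose, matching screening
#' conventions.
#'
#' @param curve a [dose_response_curve()].
#' @param level effect level defining GI50 (default 50, percent scale).
#' @param max_dose maximum tested dose (nM), used to report censored values.
#' @return A list of class `gi50_estimate` with `dose` (nM; `Inf` when
#'   censored above), `censored` (logical) and `label` (e.g. `"> 1000"`).
#' @export
gi50 <- function(curve, level = 50, max_dose = NA) {
  stopifnot(inherits(curve, "drc_4pl"))
  if (level >= curve$top) {
    lab <- if (is.na(max_dose)) "> max tested dose" else paste(">", format(max_dose))
    return(structure(list(dose = Inf, censored = TRUE, label = lab),
                     class = "gi50_estimate"))
  }
  if (level <= curve$bottom) {
    lab <- if (is.na(max_dose)) "< min tested dose" else paste("<", format(0))
    return(structure(list(dose = 0, censored = TRUE, label = lab),
                     class = "gi50_estimate"))
  }
  f <- (level - curve$bottom) / (curve$top - level)
  structure(list(dose = curve$ec50 * f^(1 / curve$hill), censored = FALSE,
                 label = NA_character_), class = "gi50_estimate")
}

#' @export
print.gi50_estimate <- function(x, ...) {
  if (x$censored) cat("GI50:", x$label, "(censored)\n")
  else cat(sprintf("GI50: %.4g nM\n", x$dose))
  invisible(x)
}

#' Convert between percent and fraction effect scales
#'
#' @param x effects (numeric) or a `drc_4pl` curve.
#' @return Rescaled effects or curve.
#' @export
effect_as_fraction <- function(x) {
  if (inherits(x, "drc_4pl"))
    return(dose_response_curve(x$top / 100, x$bottom / 100, x$ec50, x$hill,
                               x$diagnostics))
  x / 100
}

#' @rdname effect_as_fraction
#' @export
effect_as_percent <- function(x) {
  if (inherits(x, "drc_4pl"))
    return(dose_response_curve(x$top * 100, x$bottom * 100, x$ec50, x$hill,
                               x$diagnostics))
  x * 100
}
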