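# Isobologram extraction: constant-effect contours of a two-drug response
# surface. Interpolation is done on the log-dose lattice (where the grid is
# regular) with monotone cubic splines; straightness is assessed in linear
# dose space, where Loewe additivity predicts straight isoboles.

.iso_cross <- function(log_d, eff, level) {
  # First crossing of `level` along a monotone-ish profile, by monotone
  # cubic interpolation of the logit-transformed effect in log-dose (a
  # 4PL with full asymptotes is exactly linear in these coordinates, so
  # the interpolation error on sigmoid profiles is tiny); returns
  # log-dose or NA.
  if (all(eff < level) || all(eff > level)) return(NA_real_)
  eps <- 1e-9
  z <- stats::qlogis(pmin(pmax(eff, eps), 1 - eps))
  zl <- stats::qlogis(min(max(level, eps), 1 - eps))
  sf <- splinefun(log_d, z, method = "monoH.FC")
  s <- sign(z - zl)
  j <- which(s[-1] * s[-length(s)] <= 0)[1]
  if (is.na(j)) return(NA_real_)
  if (s[j] == 0) return(log_d[j])
  uniroot(function(x) sf(x) - zl, c(log_d[j], log_d[j + 1]),
          tol = 1e-10)$root
}

#' Extract an isobole (constant-effect contour)
#'
#' Finds the contour of the observed response surface at a fixed fractional
#' effect level by sweeping rows and columns of the dose lattice and
#' solving for the crossing dose with monotone cubic interpolation in
#' log-dose. Points are returned ordered along the contour in linear dose.
#' When single-agent curves are available (from a [build_surface()] input),
#' the Loewe reference line connecting the single-agent iso-effective doses
#' `(D_A(level), 0)` and `(0, D_B(level))` is attached.
#'
#' @param x a [dose_grid()] or [build_surface()] result.
#' @param level fractional effect level (default 0.70, the conventional
#'   isobologram display level).
#' @return An object of class `isobologram`: `level`, `points` (data frame
#'   with `dose_a`, `dose_b` in nM), `achieved` flag (FALSE with an empty
#'   contour when the level is never reached), and `loewe_ref` (the
#'   reference line endpoints, or NULL).
#' @export
isobole <- function(x, level = 0.70) {
  if (inherits(x, "synergy_surface")) {
    obs <- x$observed; da <- x$doses_a; db <- x$doses_b
    curve_a <- x$curve_a; curve_b <- x$curve_b
  } else if (inherits(x, "dose_grid")) {
    obs <- x$effects; da <- x$doses_a; db <- x$doses_b
    curve_a <- NULL; curve_b <- NULL
  } else stop("`x` must be a dose_grid or synergy_surface")
  if (level <= 0 || level >= 1) stop("`level` must be a fraction in (0, 1)")

  ia <- which(da > 0); ib <- which(db > 0)
  lda <- log10(da[ia]); ldb <- log10(db[ib])
  m <- obs[ia, ib, drop = FALSE]
  if (max(m) < level) {
    return(structure(list(level = level,
                          points = data.frame(dose_a = numeric(0),
                                              dose_b = numeric(0)),
                          achieved = FALSE, loewe_ref = NULL),
                     class = "isobologram"))
  }
  pts <- list()
  for (j in seq_along(ldb)) {               # sweep columns: solve for dose_a
    la <- .iso_cross(lda, m[, j], level)
    if (!is.na(la)) pts[[length(pts) + 1L]] <- c(10^la, 10^ldb[j])
  }
  for (i in seq_along(lda)) {               # sweep rows: solve for dose_b
    lb <- .iso_cross(ldb, m[i, ], level)
    if (!is.na(lb)) pts[[length(pts) + 1L]] <- c(10^lda[i], 10^lb)
  }
  if (!length(pts)) {
    return(structure(list(level = level,
                          points = data.frame(dose_a = numeric(0),
                                              dose_b = numeric(0)),
                          achieved = FALSE, loewe_ref = NULL),
                     class = "isobologram"))
  }
  p <- do.call(rbind, pts)
  p <- unique(round(p, 10))
  # order along the contour: decreasing dose_a, increasing dose_b
  p <- p[order(-p[, 1], p[, 2]), , drop = FALSE]
  loewe_ref <- NULL
  if (!is.null(curve_a) && !is.null(curve_b)) {
    d_a <- invert_curve(curve_a, level)
    d_b <- invert_curve(curve_b, level)
    loewe_ref <- list(dose_a = unname(d_a), dose_b = unname(d_b))
  }
  structure(list(level = level,
                 points = data.frame(dose_a = p[, 1], dose_b = p[, 2]),
                 achieved = TRUE, loewe_ref = loewe_ref),
            class = "isobologram")
}

#' @export
print.isobologram <- function(x, ...) {
  cat(sprintf("isobologram at %.0f%% effect: %d points (%s)\n",
              100 * x$level, nrow(x$points),
              if (x$achieved) "achieved" else "level never reached"))
  invisible(x)
}

#' Straightness of an isobole in linear dose space
#'
#' Under Loewe additivity the isoboles of a response surface are straight
#' lines in linear dose space. This measures the maximum perpendicular
#' deviation of the contour points from the chord connecting the contour's
#' two extreme points, as a fraction of the chord length (0 = perfectly
#' straight). Synergistic surfaces bow inside the chord, toward the
#' origin (positive signed deviation).
#'
#' @param iso an [isobole()] result with at least 3 points.
#' @return A list with `max_deviation` (fraction of chord length),
#'   `signed_deviation` (positive = bowed toward the origin, i.e.
#'   synergy) and `chord_length`.
#' @export
isobole_straightness <- function(iso) {
  stopifnot(inherits(iso, "isobologram"))
  p <- as.matrix(iso$points)
  if (nrow(p) < 3) stop("need at least 3 contour points")
  a <- p[1, ]; b <- p[nrow(p), ]
  chord <- b - a
  len <- sqrt(sum(chord^2))
  if (len <= 0) stop("degenerate chord")
  # signed perpendicular distance; sign > 0 means toward the origin side
  d <- ((p[, 1] - a[1]) * chord[2] - (p[, 2] - a[2]) * chord[1]) / len
  origin_side <- sign((0 - a[1]) * chord[2] - (0 - a[2]) * chord[1])
  d_signed <- d * origin_side   # positive = same side as the origin
  list(max_deviation = max(abs(d)) / len,
       signed_deviation = d_signed[which.max(abs(d_signed))] / len,
       chord_length = len)
}
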