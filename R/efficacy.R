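# In-vivo efficacy metrics on longitudinal tumor-volume tables: per-animal
# log2 exponential growth fits, AUC-per-day %TGI, and progression-free
# survival from tumor doubling (or death).

#' Tumor cohort container
#'
#' Validates a tidy longitudinal tumor-volume table with columns `animal`,
#' `group`, `day`, `volume` (mm3). Optionally a `death_day` column (or
#' attribute table) marks animals that died on study; death days are used
#' by [pfs()]. Volumes must be positive, days non-negative and strictly
#' increasing within each animal, and each animal must belong to exactly
#' one group.
#'
#' @param data a data frame with columns `animal`, `group`, `day`,
#'   `volume` (and optionally `death_day`).
#' @return The validated data frame with class `tumor_cohort`.
#' @export
tumor_cohort <- function(data) {
  need <- c("animal", "group", "day", "volume")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(data$volume)) || any(data$volume <= 0))
    stop("volumes must be positive")
  if (any(data$day < 0)) stop("days must be non-negative")
  by_animal <- split(data, data$animal)
  for (a in by_animal) {
    if (any(diff(a$day) <= 0))
      stop("days must be strictly increasing within each animal (animal ",
           a$animal[1], ")")
    if (length(unique(a$group)) != 1L)
      stop("animal ", a$animal[1], " appears in more than one group")
  }
  structure(as.data.frame(data), class = c("tumor_cohort", "data.frame"))
}

#' Fit exponential growth curves to a tumor cohort
#'
#' Ordinary least squares per animal on log2(volume) versus day, then group
#' curves as the mean of the per-animal fits (a transparent stand-in for a
#' linear mixed-effects fit: in balanced designs the group mean slope
#' coincides with the fixed-effect slope). Animals with fewer than 3
#' timepoints are excluded with a warning.
#'
#' @param cohort a [tumor_cohort()].
#' @return An object of class `growth_fit`: `animals` (data frame with
#'   `animal`, `group`, `intercept` (log2 mm3), `slope` (log2 units/day),
#'   `n_points`), `groups` (data frame with mean intercept/slope, n, and
#'   the shared fit window), and `method = "per-animal OLS"`.
#' @export
fit_growth <- function(cohort) {
  stopifnot(inherits(cohort, "tumor_cohort"))
  by_animal <- split(cohort, cohort$animal)
  keep <- vapply(by_animal, nrow, integer(1)) >= 3L
  if (any(!keep))
    warning(sum(!keep), " animal(s) with < 3 timepoints excluded")
  by_animal <- by_animal[keep]
  if (!length(by_animal)) stop("no animal has >= 3 timepoints")
  rows <- lapply(by_animal, function(a) {
    fit <- lm(log2(volume) ~ day, data = a)
    data.frame(animal = a$animal[1], group = a$group[1],
               intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
               n_points = nrow(a), day_min = min(a$day), day_max = max(a$day))
  })
  animals <- do.call(rbind, rows)
  rownames(animals) <- NULL
  groups <- do.call(rbind, lapply(split(animals, animals$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g),
               intercept = mean(g$intercept), slope = mean(g$slope),
               day_min = max(g$day_min), day_max = min(g$day_max))
  }))
  rownames(groups) <- NULL
  structure(list(animals = animals, groups = groups,
                 method = "per-animal OLS on log2(volume), group mean"),
            class = "growth_fit")
}

#' Percent tumor growth inhibition (%TGI)
#'
#' Computes `%TGI = 100 * [1 - (AUC_treatment/day) / (AUC_vehicle/day)]`
#' from the fitted group growth curves. The AUC is taken on the
#' back-transformed (linear mm3) fitted volumes by trapezoid integration on
#' a daily grid over the shared window (log2-scale AUC is selectable).
#' The AUC is taken on the raw fitted volume (not baseline-subtracted), so
#' %TGI approaches 100% from below as tumors regress.
#'
#' @param cohort a [tumor_cohort()].
#' @param treated_group,vehicle_group group labels.
#' @param window length-2 day window; defaults to the overlap of the two
#'   groups' fit windows.
#' @param scale `"linear"` (default) or `"log2"`: volume scale on which the
#'   AUC is computed.
#' @return A list of class `tgi_result`: `tgi` (percent), per-group
#'   `auc_per_day`, the window used, and the fit metadata (including the
#'   mixed-effects-substitution note).
#' @export
tgi <- function(cohort, treated_group, vehicle_group, window = NULL,
                scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  fit <- fit_growth(cohort)
  g <- fit$groups
  for (lab in c(treated_group, vehicle_group))
    if (!lab %in% g$group) stop("group not found: ", lab)
  gt <- g[g$group == treated_group, ]
  gv <- g[g$group == vehicle_group, ]
  if (is.null(window))
    window <- c(max(gt$day_min, gv$day_min), min(gt$day_max, gv$day_max))
  if (diff(window) <= 0) stop("groups have no overlapping day window")
  days <- seq(window[1], window[2], by = min(1, diff(window)))
  curve_of <- function(grp) {
    l2 <- grp$intercept + grp$slope * days
    if (scale == "linear") 2^l2 else l2
  }
  auc_per_day <- function(y) .trapz(days, y) / diff(window)
  a_t <- auc_per_day(curve_of(gt))
  a_v <- auc_per_day(curve_of(gv))
  if (abs(a_v) <= .Machine$double.eps) stop("vehicle AUC is zero; %TGI undefined")
  structure(list(
    tgi = 100 * (1 - a_t / a_v),
    auc_per_day = c(treated = a_t, vehicle = a_v),
    window = window, scale = scale, fit_method = fit$method),
    class = "tgi_result")
}

#' @export
print.tgi_result <- function(x, ...) {
  cat(sprintf("%%TGI = %.2f%%  (window %g-%g d, %s-scale AUC, %s)\n",
              x$tgi, x$window[1], x$window[2], x$scale, x$fit_method))
  invisible(x)
}

#' Progression-free survival from tumor doubling or death
#'
#' Per animal, the event time is the earliest day at which tumor volume
#' reaches `threshold_fold` times the baseline (volume at the first
#' observed day), interpolated on the log2-volume scale between
#' measurements (exact for exponential growth), or the animal's death day
#' if earlier. Animals ending the study event-free are censored at their
#' last measurement. Group medians are Kaplan-Meier medians.
#'
#' @param cohort a [tumor_cohort()]; deaths are taken from a `death_day`
#'   column when present (NA = no death).
#' @param threshold_fold progression threshold as a fold-change of baseline
#'   volume (default 2 = doubling).
#' @return An object of class `pfs_result`: `events` (data frame with
#'   `animal`, `group`, `time`, `event` (1 = progression/death,
#'   0 = censored), `cause`), and `medians` (per-group Kaplan-Meier median
#'   PFS in days).
#' @export
pfs <- function(cohort, threshold_fold = 2) {
  stopifnot(inherits(cohort, "tumor_cohort"))
  if (threshold_fold <= 1) stop("`threshold_fold` must exceed 1")
  by_animal <- split(cohort, cohort$animal)
  rows <- lapply(by_animal, function(a) {
    a <- a[order(a$day), ]
    base <- a$volume[1]
    if (!is.finite(base) || base <= 0) {
      warning("animal ", a$animal[1], " has no usable baseline; excluded")
      return(NULL)
    }
    death <- if ("death_day" %in% names(a)) a$death_day[1] else NA_real_
    l2 <- log2(a$volume / base)
    thr <- log2(threshold_fold)
    cross <- NA_real_
    hit <- which(l2 >= thr)
    if (length(hit)) {
      i <- hit[1]
      if (i == 1L) cross <- a$day[1]
      else cross <- a$day[i - 1] + (thr - l2[i - 1]) *
          (a$day[i] - a$day[i - 1]) / (l2[i] - l2[i - 1])
    }
    t_candidates <- c(doubling = cross, death = death)
    if (all(is.na(t_candidates))) {
      data.frame(animal = a$animal[1], group = a$group[1],
                 time = max(a$day), event = 0L, cause = "censored")
    } else {
      j <- which.min(t_candidates)
      data.frame(animal = a$animal[1], group = a$group[1],
                 time = unname(t_candidates[j]), event = 1L,
                 cause = names(t_candidates)[j])
    }
  })
  events <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(events) <- NULL
  medians <- vapply(split(events, events$group), function(g) {
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = g)
    unname(summary(sf)$table["median"])
  }, numeric(1))
  structure(list(events = events, medians = medians,
                 threshold_fold = threshold_fold), class = "pfs_result")
}

#' @export
print.pfs_result <- function(x, ...) {
  cat(sprintf("PFS (threshold %gx baseline):\n", x$threshold_fold))
  for (g in names(x$medians))
    cat(sprintf("  %s: median %.2f d (%d animals, %d events)\n", g,
                x$medians[g], sum(x$events$group == g),
                sum(x$events$event[x$events$group == g])))
  invisible(x)
}
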