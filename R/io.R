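# Delimited-file interchange for dose matrices, synergy surfaces and tumor
# cohorts. The dose-matrix dialect: first column = drug A doses (nM), header
# row = drug B doses (nM), cells = fractional effect; a JSON sidecar
# (`<path>.json`) carries provenance and units.

#' Write / read a dose grid as CSV
#'
#' @param grid a [dose_grid()].
#' @param path CSV path; a `<path>.json` metadata sidecar is written too.
#' @return `write_dose_grid()` returns `path` invisibly; `read_dose_grid()`
#'   returns a [dose_grid()].
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  m <- cbind(dose_a = grid$doses_a, as.data.frame(grid$effects))
  names(m)[-1] <- as.character(grid$doses_b)
  utils::write.csv(m, path, row.names = FALSE)
  meta <- list(units = "nM doses, fractional effect",
               drug_a = grid$drug_a, drug_b = grid$drug_b,
               provenance = grid$provenance)
  truth <- attr(grid, "truth")
  if (!is.null(truth))
    meta$truth <- list(null = truth$null, sd = truth$sd, seed = truth$seed,
                       bump_amplitude = truth$bump_amplitude)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  m <- utils::read.csv(path, check.names = FALSE)
  doses_a <- m[[1]]
  doses_b <- as.numeric(names(m)[-1])
  eff <- as.matrix(m[, -1, drop = FALSE])
  dimnames(eff) <- NULL
  meta_path <- paste0(path, ".json")
  prov <- "measured"; da <- "A"; db <- "B"
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    prov <- meta$provenance %||% prov
    da <- meta$drug_a %||% da; db <- meta$drug_b %||% db
  }
  dose_grid(doses_a, doses_b, eff, provenance = prov,
            drug_a = da, drug_b = db)
}

#' Write a synergy surface bundle
#'
#' Writes `observed.csv`, `expected.csv`, `excess.csv` and `score.json`
#' into a directory.
#'
#' @param surface a [build_surface()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_surface <- function(surface, dir) {
  stopifnot(inherits(surface, "synergy_surface"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  put <- function(m, f) {
    df <- cbind(dose_a = surface$doses_a, as.data.frame(m))
    names(df)[-1] <- as.character(surface$doses_b)
    utils::write.csv(df, file.path(dir, f), row.names = FALSE)
  }
  put(surface$observed, "observed.csv")
  put(surface$expected, "expected.csv")
  put(surface$excess, "excess.csv")
  jsonlite::write_json(
    list(score = surface$score, weighting = surface$weighting,
         null_model = surface$null_model,
         curve_a = surface$curve_a[c("top", "bottom", "ec50", "hill")],
         curve_b = surface$curve_b[c("top", "bottom", "ec50", "hill")]),
    file.path(dir, "score.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write / read a tumor cohort table
#'
#' Tidy CSV with columns `animal`, `group`, `day`, `volume` (mm3) and
#' optionally `death_day`.
#'
#' @param cohort a [tumor_cohort()].
#' @param path CSV path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a
#'   [tumor_cohort()].
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "tumor_cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tumor_cohort(utils::read.csv(path))
}
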