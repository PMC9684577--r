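# Domain types and CSV plumbing for per-eye paired tonometry records.
#
# A cohort is a plain data.frame (class "iop_cohort") with one row per eye:
#   subject_id, age, cct_um, r_mm, km_D, iop_gat, iop_dct
# Units: age years, CCT micrometres, radius millimetres, keratometry
# diopters, IOP mmHg. One eye per subject; subject_id unique.

# validity box for a single record; r_mm/km_D may be NA
.RECORD_BOUNDS <- list(
  age     = c(1, 120),
  cct_um  = c(350, 750),
  iop_gat = c(0, 80),   # open interval
  iop_dct = c(0, 80),   # open interval
  r_mm    = c(5, 11)
)

# default keratometric index 1.3375 => R = 337.5 / Km
.KERATOMETRIC_CONSTANT <- 337.5

.COLUMN_ALIASES <- list(
  subject_id = c("subject_id", "id", "subject", "patient_id"),
  age        = c("age", "age_years"),
  cct_um     = c("cct_um", "cct", "pachymetry_um"),
  r_mm       = c("r_mm", "r", "radius_mm"),
  km_D       = c("km_d", "km", "keratometry_d", "km_diopters"),
  iop_gat    = c("iop_gat", "gat", "gat_mmhg"),
  iop_dct    = c("iop_dct", "dct", "dct_mmhg")
)

.tc_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "tonocorr_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Convert mean keratometry to corneal radius of curvature
#'
#' Uses the standard keratometric index convention `R = k / Km` with
#' `k = 337.5` mm*D (index 1.3375, the Pentacam default), so a 43.27 D
#' cornea has a radius of about 7.80 mm.
#'
#' @param km_D Mean keratometry in diopters; must be positive.
#' @param k Keratometric constant in mm*D (default 337.5).
#' @return Radius of curvature in millimetres.
#' @seealso [radius_to_km()]
#' @export
km_to_radius <- function(km_D, k = .KERATOMETRIC_CONSTANT) {
  if (any(!is.finite(km_D)) || any(km_D <= 0)) {
    .tc_stop("tonocorr_domain_error", "km_to_radius: km_D must be positive and finite")
  }
  k / km_D
}

#' Convert corneal radius of curvature to mean keratometry
#'
#' Inverse of [km_to_radius()]: `Km = k / R` with `k = 337.5` mm*D.
#'
#' @param r_mm Radius of curvature in millimetres; must be positive.
#' @param k Keratometric constant in mm*D (default 337.5).
#' @return Mean keratometry in diopters.
#' @export
radius_to_km <- function(r_mm, k = .KERATOMETRIC_CONSTANT) {
  if (any(!is.finite(r_mm)) || any(r_mm <= 0)) {
    .tc_stop("tonocorr_domain_error", "radius_to_km: r_mm must be positive and finite")
  }
  k / r_mm
}

.check_range <- function(value, field, row, closed = TRUE) {
  b <- .RECORD_BOUNDS[[field]]
  bad <- if (closed) value < b[1] | value > b[2] else value <= b[1] | value >= b[2]
  if (isTRUE(bad)) {
    .tc_stop("tonocorr_validation_error",
             "row %d: %s = %g outside valid range [%g, %g]",
             row, field, value, b[1], b[2])
  }
  invisible(TRUE)
}

.validate_row <- function(rec, row) {
  for (f in c("age", "cct_um", "iop_gat", "iop_dct")) {
    v <- rec[[f]]
    if (is.null(v) || is.na(v)) {
      .tc_stop("tonocorr_validation_error", "row %d: missing value for %s", row, f)
    }
    .check_range(v, f, row, closed = !(f %in% c("iop_gat", "iop_dct")))
  }
  if (!is.na(rec[["r_mm"]])) .check_range(rec[["r_mm"]], "r_mm", row)
  if (!is.na(rec[["r_mm"]]) && !is.na(rec[["km_D"]])) {
    implied <- km_to_radius(rec[["km_D"]])
    if (abs(implied - rec[["r_mm"]]) > 0.01) {
      .tc_stop("tonocorr_validation_error",
               "row %d: r_mm (%g) inconsistent with km_D (%g => r = %.4f mm)",
               row, rec[["r_mm"]], rec[["km_D"]], implied)
    }
  }
  invisible(TRUE)
}

#' Construct a validated cohort of per-eye tonometry records
#'
#' @param records A data.frame with columns `subject_id`, `age`, `cct_um`,
#'   `iop_gat`, `iop_dct` and optionally `r_mm` and/or `km_D`. When `km_D`
#'   is present but `r_mm` is absent the radius is filled in via
#'   [km_to_radius()].
#' @param label Cohort label used in reports.
#' @return An object of class `iop_cohort` (a data.frame).
#' @details Every row is validated: age in \[1, 120\] years, CCT in
#'   \[350, 750\] micrometres, both IOP readings in (0, 80) mmHg, radius
#'   in \[5, 11\] mm when present, and `r_mm` consistent with `km_D` to
#'   0.01 mm when both are given. `subject_id` must be unique (one eye
#'   per subject).
#' @export
iop_cohort <- function(records, label = "cohort") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) == 0) {
    .tc_stop("tonocorr_validation_error", "cohort must contain at least one record")
  }
  for (f in c("subject_id", "age", "cct_um", "iop_gat", "iop_dct")) {
    if (!f %in% names(records)) {
      .tc_stop("tonocorr_schema_error", "missing mandatory column: %s", f)
    }
  }
  if (!"r_mm" %in% names(records)) records$r_mm <- NA_real_
  if (!"km_D" %in% names(records)) records$km_D <- NA_real_
  records$subject_id <- as.character(records$subject_id)
  for (f in c("age", "cct_um", "r_mm", "km_D", "iop_gat", "iop_dct")) {
    records[[f]] <- as.numeric(records[[f]])
  }
  fill <- is.na(records$r_mm) & !is.na(records$km_D)
  records$r_mm[fill] <- km_to_radius(records$km_D[fill])
  if (anyDuplicated(records$subject_id)) {
    .tc_stop("tonocorr_validation_error", "subject_id values must be unique (one eye per subject)")
  }
  for (i in seq_len(nrow(records))) .validate_row(records[i, ], i)
  records <- records[, c("subject_id", "age", "cct_um", "r_mm", "km_D",
                         "iop_gat", "iop_dct")]
  structure(records, label = label,
            class = c("iop_cohort", "data.frame"))
}

#' @export
print.iop_cohort <- function(x, ...) {
  cat(sprintf("<iop_cohort> %s: %d eyes\n", attr(x, "label"), nrow(x)))
  cat(sprintf("  age  %.2f +/- %.2f y | CCT %.1f +/- %.1f um\n",
              mean(x$age), stats::sd(x$age), mean(x$cct_um), stats::sd(x$cct_um)))
  cat(sprintf("  GAT  %.2f +/- %.2f mmHg | DCT %.2f +/- %.2f mmHg | DCT-GAT %.2f +/- %.2f mmHg\n",
              mean(x$iop_gat), stats::sd(x$iop_gat),
              mean(x$iop_dct), stats::sd(x$iop_dct),
              mean(x$iop_dct - x$iop_gat), stats::sd(x$iop_dct - x$iop_gat)))
  invisible(x)
}

.canonical_names <- function(nms) {
  out <- character(length(nms))
  lowered <- tolower(trimws(nms))
  for (i in seq_along(nms)) {
    hit <- NA_character_
    for (canon in names(.COLUMN_ALIASES)) {
      if (lowered[i] %in% .COLUMN_ALIASES[[canon]]) { hit <- canon; break }
    }
    out[i] <- if (is.na(hit)) nms[i] else hit
  }
  out
}

#' Read a cohort from CSV
#'
#' Reads a comma-separated file with header
#' `subject_id,age,cct_um,r_mm,km_D,iop_gat,iop_dct` (common aliases such
#' as `gat`, `dct`, `cct`, `km` are accepted; `r_mm` and `km_D` may be
#' blank). Rows are validated as in [iop_cohort()]; row order is
#' preserved; `km_D` is converted to `r_mm` when the radius is absent.
#'
#' @param path Path to the CSV file.
#' @param label Cohort label; defaults to the file name.
#' @return An `iop_cohort`.
#' @export
read_cohort <- function(path, label = basename(path)) {
  if (!file.exists(path)) {
    .tc_stop("tonocorr_schema_error", "file not found: %s", path)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  names(raw) <- .canonical_names(names(raw))
  iop_cohort(raw, label = label)
}

#' Write a cohort to CSV
#'
#' Writes the canonical schema `subject_id,age,cct_um,r_mm,km_D,iop_gat,iop_dct`
#' with blanks for missing optional fields; reading the file back with
#' [read_cohort()] reproduces the cohort.
#'
#' @param cohort An `iop_cohort`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "iop_cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}
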