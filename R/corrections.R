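# Registry of published GAT correction formulas.
#
# Each formula maps a Goldmann applanation reading (plus central corneal
# thickness, radius of curvature and/or age) to a corneal-property-adjusted
# IOP estimate. All formulas are pure functions of one record; constants are
# overridable per call. CCT enters in micrometres at the interface; the
# formulas that were published in millimetre units convert internally.

.polyval <- function(coef, x) {
  # coef in ascending order: coef[1] + coef[2]*x + ...
  out <- 0
  for (j in rev(seq_along(coef))) out <- out * x + coef[j]
  out
}

.default_elsheikh_coef <- function() {
  # Coefficient polynomials for the multiplicative corneal-response factors
  # A_CCT, A_R, A_age, A_IOP are not in the public domain here; defaults are
  # identity (constant 1). Users supply ascending polynomial coefficients.
  list(a_cct = 1, a_r = 1, a_age = 1, a_iop = 1)
}

.shimmyo_delta <- function(gat, cct_um, variant) {
  base <- (550 - cct_um)
  switch(variant,
    linear  = base / 18,
    power   = base / 18 ^ (0.005 * gat),
    literal = base / 18 ^ (-0.005 * gat),
    .tc_stop("tonocorr_usage_error",
             "unknown shimmyo variant '%s' (use linear, power or literal)", variant)
  )
}

# --- formula registry -------------------------------------------------------

.FORMULAS <- list(
  shimmyo = list(
    label = "Shimmyo", requires = c("cct"),
    params = list(variant = "linear"),
    fn = function(gat, cct_um, r_mm, age, p) {
      gat + .shimmyo_delta(gat, cct_um, p$variant)
    }
  ),
  shimmyo_r = list(
    label = "ShimmyoR", requires = c("cct", "r"),
    params = list(variant = "linear", r_ref = 7.848837, r_slope = 0.8),
    fn = function(gat, cct_um, r_mm, age, p) {
      gat + .shimmyo_delta(gat, cct_um, p$variant) + p$r_slope * (r_mm - p$r_ref)
    }
  ),
  elsheikh2009 = list(
    label = "Elsheikh2009", requires = c("cct", "r", "age"),
    params = list(coef = NULL),
    fn = function(gat, cct_um, r_mm, age, p) {
      cf <- if (is.null(p$coef)) .default_elsheikh_coef() else p$coef
      denom <- .polyval(cf$a_cct, cct_um) * .polyval(cf$a_r, r_mm) *
        .polyval(cf$a_age, age) * .polyval(cf$a_iop, gat)
      if (any(denom <= 0)) {
        .tc_stop("tonocorr_numeric_error",
                 "elsheikh2009: coefficient product non-positive in validity range")
      }
      gat / denom
    }
  ),
  elsheikh2011 = list(
    label = "Elsheikh2011", requires = c("cct", "r", "age"),
    params = list(coef = NULL),
    fn = function(gat, cct_um, r_mm, age, p) {
      cf <- if (is.null(p$coef)) .default_elsheikh_coef() else p$coef
      denom <- .polyval(cf$a_cct, cct_um) * .polyval(cf$a_r, r_mm) *
        .polyval(cf$a_age, age) * .polyval(cf$a_iop, gat)
      if (any(denom <= 0)) {
        .tc_stop("tonocorr_numeric_error",
                 "elsheikh2011: coefficient product non-positive in validity range")
      }
      gat / denom
    }
  ),
  srodka = list(
    label = "Srodka", requires = c("cct", "r"),
    params = list(e = 1, cct_c = 0.550, r_c = 7.8,
                  cal = c(-1.61, 0.94, 0.011)),
    fn = function(gat, cct_um, r_mm, age, p) {
      cct_mm <- cct_um / 1000
      iop_ca <- .polyval(p$cal, gat)
      mult <- p$e * (p$cct_c - (r_mm / p$r_c) * cct_mm) + 1
      mult * (iop_ca + 3) - 3
    }
  ),
  chihara = list(
    label = "Chihara", requires = c("cct", "r"),
    params = list(a = 0.34, units = "mm"),
    fn = function(gat, cct_um, r_mm, age, p) {
      cct <- switch(p$units,
        mm = cct_um / 1000,
        um = cct_um,
        .tc_stop("tonocorr_usage_error", "chihara units must be 'mm' or 'um'"))
      frac <- 19.09 * cct^2 / (p$a * (r_mm * 1e3 - cct / 2) * 1e4)
      (gat + 4.15) / (frac + 1)
    }
  ),
  doughty = list(
    label = "Doughty", requires = c("cct"),
    params = list(cct_ref = 545, scale = 25),
    fn = function(gat, cct_um, r_mm, age, p) {
      gat + p$scale * (p$cct_ref - cct_um) / p$cct_ref
    }
  ),
  foster = list(
    label = "Foster", requires = character(0),
    params = list(slope = 1.08, intercept = 5.5),
    fn = function(gat, cct_um, r_mm, age, p) {
      p$slope * gat + p$intercept
    }
  ),
  kohlhaas = list(
    label = "Kohlhaas", requires = c("cct"),
    params = list(slope = -0.0423, intercept = 23.28),
    fn = function(gat, cct_um, r_mm, age, p) {
      gat + (p$slope * cct_um + p$intercept)
    }
  ),
  ehlers = list(
    label = "Ehlers", requires = c("cct"),
    params = list(slope = 0.071, cct_ref = 520),
    fn = function(gat, cct_um, r_mm, age, p) {
      gat + p$slope * (p$cct_ref - cct_um)
    }
  )
)

#' List the available GAT correction formulas
#'
#' @return A data.frame with one row per registered formula: its id, a
#'   human-readable label, the biometric inputs it requires beyond the GAT
#'   reading, and the names of its overridable constants.
#' @export
correction_formulas <- function() {
  data.frame(
    formula_id = names(.FORMULAS),
    label = vapply(.FORMULAS, `[[`, "", "label"),
    requires = vapply(.FORMULAS, function(f)
      paste(f$requires, collapse = ","), ""),
    params = vapply(.FORMULAS, function(f)
      paste(names(f$params), collapse = ","), ""),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

.get_formula <- function(formula_id) {
  f <- .FORMULAS[[formula_id]]
  if (is.null(f)) {
    .tc_stop("tonocorr_usage_error",
             "unknown formula id '%s'; available: %s",
             formula_id, paste(names(.FORMULAS), collapse = ", "))
  }
  f
}

.require_inputs <- function(f, formula_id, cct_um, r_mm, age) {
  need <- f$requires
  if ("cct" %in% need && any(is.na(cct_um))) {
    .tc_stop("tonocorr_dependency_error", "formula '%s' requires cct_um", formula_id)
  }
  if ("r" %in% need && any(is.na(r_mm))) {
    .tc_stop("tonocorr_dependency_error", "formula '%s' requires r_mm (or km_D)", formula_id)
  }
  if ("age" %in% need && any(is.na(age))) {
    .tc_stop("tonocorr_dependency_error", "formula '%s' requires age", formula_id)
  }
  invisible(TRUE)
}

#' Apply a GAT correction formula to a single reading
#'
#' @param formula_id One of the ids in [correction_formulas()].
#' @param gat GAT IOP reading, mmHg.
#' @param cct_um Central corneal thickness, micrometres (formulas needing
#'   millimetres convert internally).
#' @param r_mm Corneal radius of curvature, millimetres.
#' @param age Age in years.
#' @param params Named list of constant overrides merged over the
#'   registry defaults (e.g. `list(variant = "power")` for Shimmyo, or
#'   `list(coef = ...)` polynomial coefficient lists for Elsheikh).
#' @return Corrected IOP in mmHg. Never `NaN`: missing required inputs and
#'   degenerate parameterizations raise classed errors; a non-positive
#'   corrected value triggers a warning but is returned unclamped.
#' @examples
#' correct("kohlhaas", gat = 15, cct_um = 525)   # 16.0725
#' correct("foster", gat = 15.5)                 # 22.24
#' @export
correct <- function(formula_id, gat, cct_um = NA_real_, r_mm = NA_real_,
                    age = NA_real_, params = list()) {
  f <- .get_formula(formula_id)
  .require_inputs(f, formula_id, cct_um, r_mm, age)
  p <- utils::modifyList(f$params, params)
  out <- f$fn(gat, cct_um, r_mm, age, p)
  if (any(!is.finite(out))) {
    .tc_stop("tonocorr_numeric_error", "formula '%s' produced a non-finite value", formula_id)
  }
  if (any(out <= 0)) {
    warning(sprintf("formula '%s': corrected IOP <= 0 mmHg (not clamped)", formula_id),
            call. = FALSE)
  }
  out
}

#' Apply a correction formula to every record of a cohort
#'
#' @param formula_id Formula id, see [correction_formulas()].
#' @param cohort An `iop_cohort`.
#' @param params Constant overrides as in [correct()].
#' @return Numeric vector of corrected IOP values (mmHg), aligned with the
#'   cohort's row order.
#' @export
correct_cohort <- function(formula_id, cohort, params = list()) {
  if (!inherits(cohort, "iop_cohort")) {
    .tc_stop("tonocorr_usage_error", "correct_cohort expects an iop_cohort")
  }
  if (nrow(cohort) == 0) {
    .tc_stop("tonocorr_validation_error", "empty cohort")
  }
  correct(formula_id, gat = cohort$iop_gat, cct_um = cohort$cct_um,
          r_mm = cohort$r_mm, age = cohort$age, params = params)
}
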