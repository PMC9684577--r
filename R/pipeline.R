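# End-to-end study orchestration: for a cohort (read from CSV or
# generated), correct the GAT column with every applicable formula, compare
# each corrected series against DCT (signed and absolute paired statistics,
# Bland-Altman), test normality of the difference series, and rank the
# formulas by mean absolute difference. Deterministic given cohort and
# config.

#' Study configuration
#'
#' @param formulas Character vector of formula ids to run (default: the
#'   whole registry, see [correction_formulas()]).
#' @param k Bland-Altman limits-of-agreement multiplier (default 2).
#' @param alpha Significance level for bias tests (default 0.05).
#' @param ks_n_mc Monte-Carlo replicates for the normality test.
#' @param ks_seed Seed for the normality Monte-Carlo.
#' @param formula_params Named list of per-formula constant overrides,
#'   e.g. `list(shimmyo = list(variant = "power"))`.
#' @param run_normality Whether to run normality tests on the difference
#'   series (default TRUE).
#' @return A `study_config` list.
#' @export
study_config <- function(formulas = correction_formulas()$formula_id,
                         k = 2, alpha = 0.05,
                         ks_n_mc = 2000, ks_seed = 1,
                         formula_params = list(),
                         run_normality = TRUE) {
  structure(list(formulas = formulas, k = k, alpha = alpha,
                 ks_n_mc = ks_n_mc, ks_seed = ks_seed,
                 formula_params = formula_params,
                 run_normality = run_normality),
            class = "study_config")
}

.comparison_row <- function(pc, ba) {
  data.frame(
    label = pc$label, n = pc$n,
    mean_diff = pc$mean_diff, sd_diff = pc$sd_diff,
    t_stat = pc$t_stat, p_value = pc$p_value,
    mean_absdiff = pc$mean_absdiff, sd_absdiff = pc$sd_absdiff,
    loa_low = ba$loa_low, loa_high = ba$loa_high,
    fixed_bias = ba$fixed_bias,
    prop_slope = ba$prop_slope, prop_p = ba$prop_p,
    prop_bias = ba$prop_bias,
    stringsAsFactors = FALSE
  )
}

#' Run the full method-comparison study on a cohort
#'
#' For the uncorrected GAT series and for every enabled formula whose
#' input requirements the cohort satisfies, computes DCT - GAT_corrected
#' paired statistics ([paired_compare()]), a Bland-Altman analysis
#' ([bland_altman()]), and the change in per-eye absolute error relative
#' to the uncorrected series ([compare_correction_effect()]). Formulas
#' whose requirements are unmet (e.g. no curvature column) are skipped
#' with a warning and listed in the report.
#'
#' @param cohort An `iop_cohort`.
#' @param config A [study_config()].
#' @return A `study_report` list: `cohort_summary`, `comparisons` (one row
#'   per method, signed and absolute statistics plus bias flags),
#'   `bland_altman` (named list of full results with plot coordinates),
#'   `improvement` (per-formula absolute-error change vs uncorrected),
#'   `normality`, `ranking` (labels ordered by mean absolute difference,
#'   ties broken alphabetically), `skipped`, `provenance`.
#' @export
run_study <- function(cohort, config = study_config()) {
  if (!inherits(cohort, "iop_cohort") || nrow(cohort) == 0) {
    .tc_stop("tonocorr_validation_error", "run_study needs a non-empty iop_cohort")
  }
  dct <- cohort$iop_dct
  gat <- cohort$iop_gat
  d0 <- abs(dct - gat)

  rows <- list()
  ba_list <- list()
  improvement <- list()
  skipped <- character(0)

  pc0 <- paired_compare(dct, gat, label = "uncorrected")
  ba0 <- bland_altman(dct, gat, k = config$k, alpha = config$alpha,
                      label = "uncorrected")
  rows[["uncorrected"]] <- .comparison_row(pc0, ba0)
  ba_list[["uncorrected"]] <- ba0

  for (fid in config$formulas) {
    fp <- config$formula_params[[fid]]
    if (is.null(fp)) fp <- list()
    corrected <- tryCatch(
      correct_cohort(fid, cohort, params = fp),
      tonocorr_dependency_error = function(e) {
        warning(sprintf("skipping formula '%s': %s", fid, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(corrected)) { skipped <- c(skipped, fid); next }
    lab <- .FORMULAS[[fid]]$label
    pc <- paired_compare(dct, corrected, label = lab)
    ba <- bland_altman(dct, corrected, k = config$k, alpha = config$alpha,
                       label = lab)
    rows[[fid]] <- .comparison_row(pc, ba)
    ba_list[[fid]] <- ba
    improvement[[fid]] <- compare_correction_effect(dct - gat, dct - corrected,
                                                    label = lab)
  }

  comparisons <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ord <- order(comparisons$mean_absdiff, comparisons$label)
  ranking <- comparisons$label[ord]

  normality <- NULL
  if (isTRUE(config$run_normality)) {
    normality <- list(diff_uncorrected =
      ks_normality(dct - gat, n_mc = config$ks_n_mc, seed = config$ks_seed))
  }

  structure(list(
    cohort_summary = list(
      label = attr(cohort, "label"), n = nrow(cohort),
      age = c(mean = mean(cohort$age), sd = stats::sd(cohort$age)),
      cct_um = c(mean = mean(cohort$cct_um), sd = stats::sd(cohort$cct_um)),
      iop_gat = c(mean = mean(gat), sd = stats::sd(gat)),
      iop_dct = c(mean = mean(dct), sd = stats::sd(dct))
    ),
    comparisons = comparisons,
    bland_altman = ba_list,
    improvement = improvement,
    normality = normality,
    ranking = ranking,
    skipped = skipped,
    provenance = list(
      package_version = as.character(utils::packageVersion("tonocorr")),
      formulas = setdiff(config$formulas, skipped),
      formula_params = config$formula_params,
      k = config$k, alpha = config$alpha
    )
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  s <- x$cohort_summary
  cat(sprintf("Study report: %s (n = %d eyes)\n", s$label, s$n))
  cat(sprintf("  DCT %.2f +/- %.2f | GAT %.2f +/- %.2f mmHg\n",
              s$iop_dct["mean"], s$iop_dct["sd"],
              s$iop_gat["mean"], s$iop_gat["sd"]))
  tab <- x$comparisons
  out <- data.frame(
    method = tab$label,
    `signed` = sprintf("%.2f +/- %.2f", tab$mean_diff, tab$sd_diff),
    `absolute` = sprintf("%.2f +/- %.2f", tab$mean_absdiff, tab$sd_absdiff),
    p = ifelse(tab$p_value < 0.001, "<0.001", sprintf("%.3f", tab$p_value)),
    LoA = sprintf("[%.2f, %.2f]", tab$loa_low, tab$loa_high),
    fixed = ifelse(tab$fixed_bias, "yes", "no"),
    prop = ifelse(tab$prop_bias, "yes", "no"),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  print(out, row.names = FALSE)
  if (length(x$skipped)) cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  cat("  ranking by mean |DCT - GAT_corr|:", paste(x$ranking, collapse = " < "), "\n")
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes `report.json` (full precision), `table_signed.csv` and
#' `table_absolute.csv` (2-decimal human tables of the signed and
#' absolute difference statistics), and one `blandaltman_<method>.csv`
#' of (mean, difference) coordinates per method.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- report$comparisons
  signed <- data.frame(method = tab$label, n = tab$n,
                       mean_diff = round(tab$mean_diff, 2),
                       sd_diff = round(tab$sd_diff, 2),
                       p_value = signif(tab$p_value, 3))
  absolute <- data.frame(method = tab$label, n = tab$n,
                         mean_absdiff = round(tab$mean_absdiff, 2),
                         sd_absdiff = round(tab$sd_absdiff, 2))
  utils::write.csv(signed, file.path(dir, "table_signed.csv"), row.names = FALSE)
  utils::write.csv(absolute, file.path(dir, "table_absolute.csv"), row.names = FALSE)
  for (nm in names(report$bland_altman)) {
    utils::write.csv(report$bland_altman[[nm]]$points,
                     file.path(dir, paste0("blandaltman_", nm, ".csv")),
                     row.names = FALSE)
  }
  json <- report
  json$bland_altman <- lapply(json$bland_altman, function(b) {
    b$points <- NULL
    unclass(b)
  })
  json$improvement <- lapply(json$improvement, unclass)
  json$normality <- lapply(json$normality, unclass)
  jsonlite::write_json(unclass(json), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
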