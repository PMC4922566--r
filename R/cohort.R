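#' Run the full per-subject threshold-derivation pipeline
#'
#' Executes, for one subject: temporal median CBF map → PET/white-matter/
#' vessel segmentation → per-pixel class table → class balancing → weighted
#' logistic regression and ROC analysis → optimal operating point, plus the
#' infarct rCBF time course. The pipeline is deterministic: rerunning on the
#' same inputs reproduces the result exactly.
#'
#' A subject is analyzable only if a PET uptake defect is present: the final
#' infarct grey matter must be non-empty and make up at least
#' `params$min_defect_fraction` of the affected-ROI grey matter (the
#' mean − 2 SD rule classifies ~2.3% of defect-free tissue as "infarct" by
#' chance, so a floor is needed to mirror the visual defect call). For
#' non-analyzable subjects the metrics are `NA`, mirroring animals excluded
#' from the original analysis.
#'
#' @param x A manifest path (see [read_study()]), a [registered_study()], or
#'   the result of [generate_study()].
#' @param params A [seg_params()].
#' @param include_baseline Include the pre-injection CBF map in the median
#'   and rCBF summaries (default `FALSE`).
#' @param criterion ROC optimality criterion, `"youden"` or `"closest"`.
#' @param detail If `TRUE`, return a list with the result row plus all
#'   intermediate objects (median map, masks, fit, ROC, time course).
#' @return A one-row tibble: `subject_id`, `analyzable`, pixel counts,
#'   `infarct_volume_ml`, `optimal_threshold`, `sensitivity`, `specificity`,
#'   `accuracy`, `auc`, `p75_cbf`, `p50_cbf`, `grand_mean_rcbf_pct`,
#'   `pet_threshold`, `logit_converged`.
#' @export
run_subject <- function(x, params = seg_params(), include_baseline = FALSE,
                        criterion = c("youden", "closest"), detail = FALSE) {
  criterion <- match.arg(criterion)
  study <- if (inherits(x, "registered_study")) {
    x
  } else if (is.list(x) && inherits(x$study, "registered_study")) {
    x$study
  } else if (is.character(x) && length(x) == 1L) {
    read_study(x)
  } else {
    abort("`x` must be a manifest path, a registered_study, or a generate_study() result.")
  }

  med <- median_cbf_map(study, include_baseline = include_baseline)
  seg <- withCallingHandlers(
    final_analysis_masks(study, med, params),
    warning = function(w) invokeRestart("muffleWarning")
  )

  defect_fraction <- if (seg$analyzable) {
    mask_count(seg$infarct_gm) /
      (mask_count(seg$infarct_gm) + mask_count(seg$noninfarct_gm))
  } else {
    0
  }
  analyzable <- seg$analyzable && defect_fraction >= params$min_defect_fraction

  na_row <- function() tibble(
    subject_id = study$subject_id, analyzable = FALSE,
    n_infarct_px = mask_count(seg$infarct_gm),
    n_noninfarct_px = mask_count(seg$noninfarct_gm),
    defect_fraction = defect_fraction,
    infarct_volume_ml = NA_real_, optimal_threshold = NA_real_,
    sensitivity = NA_real_, specificity = NA_real_, accuracy = NA_real_,
    auc = NA_real_, p75_cbf = NA_real_, p50_cbf = NA_real_,
    grand_mean_rcbf_pct = NA_real_,
    pet_threshold = if (length(seg$pet_threshold) == 1L) seg$pet_threshold
                    else NA_real_,
    logit_converged = NA
  )
  if (!analyzable) {
    inform(sprintf("Subject '%s': no usable PET uptake defect (infarct fraction %.1f%%); not analyzable.",
                   study$subject_id, 100 * defect_fraction))
    row <- na_row()
    if (detail) return(list(result = row, study = study, median = med, seg = seg))
    return(row)
  }

  tab <- build_class_table(med, seg$infarct_gm, seg$noninfarct_gm)
  bal <- balance_classes(tab)
  fit <- fit_logistic(bal)
  roc <- roc_curve(bal, criterion = criterion)
  opt <- roc$optimal

  contra_gm <- mask_diff(mask_diff(study$roi_contra, seg$wm), seg$vessels)
  rcbf <- infarct_rcbf_timecourse(study, seg$infarct_gm, contra_gm,
                                  include_baseline = include_baseline)

  row <- tibble(
    subject_id = study$subject_id, analyzable = TRUE,
    n_infarct_px = mask_count(seg$infarct_gm),
    n_noninfarct_px = mask_count(seg$noninfarct_gm),
    defect_fraction = defect_fraction,
    infarct_volume_ml = mask_volume_ml(seg$infarct_gm),
    optimal_threshold = opt$threshold,
    sensitivity = opt$sensitivity,
    specificity = opt$specificity,
    accuracy = opt$accuracy,
    auc = roc$auc,
    p75_cbf = if (fit$converged) probability_crossing(fit, 0.75) else NA_real_,
    p50_cbf = if (fit$converged) probability_crossing(fit, 0.5) else NA_real_,
    grand_mean_rcbf_pct = rcbf$grand_mean_pct,
    pet_threshold = if (length(seg$pet_threshold) == 1L) seg$pet_threshold
                    else NA_real_,
    logit_converged = fit$converged
  )
  if (detail) {
    return(list(result = row, study = study, median = med, seg = seg,
                table = bal, fit = fit, roc = roc, rcbf = rcbf))
  }
  row
}

cohort_metrics <- c(
  "optimal_threshold", "p75_cbf", "p50_cbf", "infarct_volume_ml",
  "auc", "sensitivity", "specificity", "accuracy", "grand_mean_rcbf_pct"
)

#' Aggregate per-subject results into a cohort summary
#'
#' Arithmetic mean, sample SD (n − 1) and standard error (SD/√n) of each
#' available metric over the analyzable subjects. A single subject yields
#' SD = SE = 0 by convention. Because "mean ± x" reports are ambiguous
#' between SD and SE, both are always given explicitly, together with n.
#'
#' @param results A data frame with one row per subject — the output of
#'   [run_subject()] rows bound together, or any table carrying a subset of
#'   the metric columns (`optimal_threshold`, `p75_cbf`, `p50_cbf`,
#'   `infarct_volume_ml`, `auc`, `sensitivity`, `specificity`, `accuracy`,
#'   `grand_mean_rcbf_pct`). An `analyzable` logical column, if present,
#'   filters the rows first.
#' @return A tibble with columns `metric`, `n`, `mean`, `sd`, `se`, plus
#'   attributes `n_total` and `n_analyzable`.
#' @examples
#' summarize_cohort(porcine_reference())
#' @export
summarize_cohort <- function(results) {
  stopifnot(is.data.frame(results))
  n_total <- nrow(results)
  if ("analyzable" %in% names(results)) {
    results <- results[isTRUE_vec(results$analyzable), ]
  }
  if (nrow(results) == 0L) {
    abort("No analyzable subjects: nothing to summarize.")
  }
  metrics <- intersect(cohort_metrics, names(results))
  if (length(metrics) == 0L) {
    abort("`results` carries none of the recognized metric columns.")
  }
  out <- purrr::map_dfr(metrics, function(m) {
    v <- results[[m]]
    v <- v[is.finite(v)]
    if (length(v) == 0L) {
      return(tibble(metric = m, n = 0L, mean = NA_real_, sd = NA_real_,
                    se = NA_real_))
    }
    s <- if (length(v) > 1L) stats::sd(v) else 0
    tibble(metric = m, n = length(v), mean = mean(v), sd = s,
           se = s / sqrt(length(v)))
  })
  attr(out, "n_total") <- n_total
  attr(out, "n_analyzable") <- nrow(results)
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Per-animal reference ROC parameters and infarct volumes
#'
#' The published per-animal results of the porcine ET-1 threshold-derivation
#' experiment this package models: for each of the six animals that
#' developed infarction, the CBF threshold at the ROC optimal operating
#' point (mL·min⁻¹·100g⁻¹), its sensitivity, specificity and accuracy, the
#' AUC, and the PET-defined grey-matter infarct volume (mL). Useful as input
#' to [summarize_cohort()] and as a plausibility band for phantom studies.
#'
#' @return A tibble with 6 rows.
#' @export
porcine_reference <- function() {
  path <- system.file("extdata", "porcine_et1_reference.csv",
                      package = "cbfcore", mustWork = TRUE)
  as_tibble(utils::read.csv(path))
}
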