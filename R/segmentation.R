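#' Pixel-classification parameters
#'
#' The constants of the three classification rules. Defaults are the study's:
#' PET infarct rule "contralateral mean minus 2 SD" (`pet_k = 2`),
#' white-matter rule "CT number below 40 HU" (`hu_min = 40`), vessel rules
#' "BV above the affected-side mean plus 2 SD" (`bv_k = 2`) or "median CBF
#' above 100 mL·min⁻¹·100g⁻¹" (`cbf_vessel_cap = 100`). All comparisons are
#' strict, exactly as the rules are stated; equality stays in the retained
#' class.
#'
#' @param pet_k PET defect depth in contralateral SDs (> 0).
#' @param hu_min Hounsfield cutoff below which pixels count as white matter.
#' @param bv_k Blood-volume multiplier of the affected-side SD (> 0).
#' @param cbf_vessel_cap Median-CBF vessel cutoff (mL·min⁻¹·100g⁻¹, > 0).
#' @param per_slice_stats Compute the contralateral PET reference statistics
#'   per slice instead of pooled over the whole ROI. Pooled is the default
#'   (and the convention used throughout); per-slice is offered for
#'   sensitivity analysis without any claim about the original procedure.
#' @param min_defect_fraction Minimum fraction of affected-ROI grey matter
#'   that must be classified infarct for a subject to count as having an
#'   uptake defect (see [run_subject()]); the chance rate of the mean − 2 SD
#'   rule on defect-free tissue is about 2.3%, so the default 0.05 separates
#'   "defect" from noise.
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(pet_k = 2, hu_min = 40, bv_k = 2, cbf_vessel_cap = 100,
                       per_slice_stats = FALSE, min_defect_fraction = 0.05) {
  if (pet_k <= 0 || bv_k <= 0 || cbf_vessel_cap <= 0) {
    abort("`pet_k`, `bv_k` and `cbf_vessel_cap` must be positive.")
  }
  structure(
    list(pet_k = pet_k, hu_min = hu_min, bv_k = bv_k,
         cbf_vessel_cap = cbf_vessel_cap,
         per_slice_stats = isTRUE(per_slice_stats),
         min_defect_fraction = min_defect_fraction),
    class = "seg_params"
  )
}

#' PET uptake-defect segmentation
#'
#' Classifies every pixel of the affected-side cortical ROI as infarct or
#' non-infarct by comparison with the contralateral ROI: the threshold is
#' `mean(contra) - pet_k * sd(contra)` (sample SD, pooled over all slices of
#' the ROI by default); affected pixels with PET signal strictly below the
#' threshold are infarct, all others non-infarct. The two output masks
#' partition the affected ROI. Pixels with non-finite PET values are dropped
#' from both classes.
#'
#' @param pet A `"PET"` [scalar_map()].
#' @param roi_affected,roi_contra Non-empty [roi_mask()]s on the same grid.
#' @param params A [seg_params()].
#' @return A list with `infarct` and `noninfarct` [roi_mask()]s and
#'   `threshold` (the PET cutoff used; a per-slice numeric vector when
#'   `per_slice_stats = TRUE`).
#' @export
pet_infarct_mask <- function(pet, roi_affected, roi_contra,
                             params = seg_params()) {
  stopifnot(inherits(pet, "scalar_map"), inherits(params, "seg_params"))
  if (mask_count(roi_contra) == 0L) {
    abort("Contralateral ROI is empty; the defect threshold is undefined.")
  }
  if (mask_count(roi_affected) == 0L) abort("Affected ROI is empty.")
  v <- pet$values
  finite <- is.finite(v)
  if (params$per_slice_stats) {
    nz <- pet$grid$shape[3]
    thr <- rep(NA_real_, nz)
    below <- array(FALSE, pet$grid$shape)
    for (k in seq_len(nz)) {
      contra_k <- roi_contra$members[, , k] & finite[, , k]
      if (!any(contra_k)) next
      vk <- v[, , k][contra_k]
      thr[k] <- mean(vk) - params$pet_k * (if (length(vk) > 1) stats::sd(vk) else 0)
      below[, , k] <- finite[, , k] & (v[, , k] < thr[k])
    }
  } else {
    st <- mask_stats(pet, roi_contra)
    thr <- st$mean - params$pet_k * st$sd
    below <- finite & (v < thr)
  }
  aff <- roi_affected$members & finite
  list(
    infarct = roi_mask(aff & below, pet$grid, "affected"),
    noninfarct = roi_mask(aff & !below, pet$grid, "affected"),
    threshold = thr
  )
}

#' White-matter exclusion mask
#'
#' Marks every pixel whose CT number on the average (perfusion-weighted)
#' image is strictly below `hu_min` (default 40 HU). Because the PET ligand
#' binds cortical grey matter, these low-attenuation pixels (white matter,
#' and any non-brain background) are excluded from the grey-matter analysis.
#'
#' @param avg_image An `"HU"` [scalar_map()].
#' @param params A [seg_params()].
#' @return An [roi_mask()]; members are the excluded pixels.
#' @export
white_matter_mask <- function(avg_image, params = seg_params()) {
  stopifnot(inherits(avg_image, "scalar_map"))
  if (avg_image$modality != "HU") {
    abort("`avg_image` must have modality \"HU\".")
  }
  v <- avg_image$values
  roi_mask(is.finite(v) & (v < params$hu_min), avg_image$grid)
}

#' Blood-vessel exclusion mask
#'
#' A pixel counts as vessel if its blood volume exceeds (strictly) the
#' affected-side ROI mean plus `bv_k` SDs — the statistic is computed on the
#' raw affected ROI, before any other exclusion — or if its median CBF
#' exceeds (strictly) `cbf_vessel_cap`. The rule is evaluated over the whole
#' volume so the mask can also be inspected contralaterally; it is applied as
#' an exclusion to the infarct and non-infarct masks.
#'
#' @param bv A `"BV"` [scalar_map()].
#' @param median_cbf A `"CBF"` [scalar_map()] or [median_cbf_map()] result.
#' @param roi_affected Non-empty [roi_mask()] supplying the BV statistic.
#' @param params A [seg_params()].
#' @return An [roi_mask()] of vessel pixels, with attribute `bv_threshold`.
#' @export
vessel_mask <- function(bv, median_cbf, roi_affected, params = seg_params()) {
  stopifnot(inherits(bv, "scalar_map"))
  if (inherits(median_cbf, "median_cbf_map")) median_cbf <- median_cbf$map
  stopifnot(inherits(median_cbf, "scalar_map"))
  if (mask_count(roi_affected) == 0L) {
    abort("Affected ROI is empty; the BV vessel threshold is undefined.")
  }
  st <- mask_stats(bv, roi_affected)
  bv_thr <- st$mean + params$bv_k * st$sd
  m <- (is.finite(bv$values) & bv$values > bv_thr) |
    (is.finite(median_cbf$values) & median_cbf$values > params$cbf_vessel_cap)
  out <- roi_mask(m, bv$grid)
  attr(out, "bv_threshold") <- bv_thr
  out
}

#' Final grey-matter analysis masks
#'
#' Combines the three rules: within the affected cortical ROI, the PET
#' infarct and non-infarct classes have white matter and vessels removed,
#' yielding the disjoint grey-matter masks that are superimposed on the
#' median CBF map for the statistical analysis. If either final mask is
#' empty the subject is flagged non-analyzable (mirroring animals without a
#' usable uptake defect).
#'
#' @param study A [registered_study()].
#' @param median_cbf A [median_cbf_map()] result (or `"CBF"` scalar map).
#' @param params A [seg_params()].
#' @return A list with `infarct_gm`, `noninfarct_gm` ([roi_mask()]s),
#'   `wm`, `vessels`, `pet_threshold`, `analyzable` (logical) and a one-row
#'   tibble `report` (thresholds, pixel counts, volumes in mL).
#' @export
final_analysis_masks <- function(study, median_cbf, params = seg_params()) {
  stopifnot(inherits(study, "registered_study"))
  pet <- pet_infarct_mask(study$pet_image, study$roi_affected,
                          study$roi_contra, params)
  wm <- white_matter_mask(study$avg_image, params)
  ves <- vessel_mask(study$bv_map, median_cbf, study$roi_affected, params)
  excl <- mask_union(wm, ves)
  infarct_gm <- mask_diff(pet$infarct, excl)
  noninfarct_gm <- mask_diff(pet$noninfarct, excl)
  analyzable <- mask_count(infarct_gm) > 0L && mask_count(noninfarct_gm) > 0L
  if (!analyzable) {
    warn(sprintf("Subject '%s': an analysis mask is empty; flagged non-analyzable.",
                 study$subject_id))
  }
  report <- tibble(
    subject_id = study$subject_id,
    pet_threshold = if (params$per_slice_stats) NA_real_ else pet$threshold,
    bv_threshold = attr(ves, "bv_threshold"),
    hu_min = params$hu_min,
    cbf_vessel_cap = params$cbf_vessel_cap,
    n_infarct_px = mask_count(infarct_gm),
    n_noninfarct_px = mask_count(noninfarct_gm),
    infarct_volume_ml = mask_volume_ml(infarct_gm),
    noninfarct_volume_ml = mask_volume_ml(noninfarct_gm)
  )
  list(
    infarct_gm = infarct_gm, noninfarct_gm = noninfarct_gm,
    wm = wm, vessels = ves, pet_threshold = pet$threshold,
    analyzable = analyzable, report = report
  )
}
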