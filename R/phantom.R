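#' Configuration of the synthetic two-hemisphere phantom
#'
#' Defines a digital phantom that reproduces the statistical structure of the
#' endothelin-1 (ET-1) porcine ischemia experiment the pipeline was designed
#' for: a grey-matter cortical ribbon (default 45 HU) around a white-matter
#' core (35 HU), a focal PET uptake defect several contralateral SDs deep, a
#' serial CBF series in which the infarct region follows a relative-CBF
#' (rCBF) time course (56% of baseline for the first 30 min, ~40% from 60 min
#' onward), mildly hypoperfused (oligemic) non-infarct grey matter on the
#' affected side, and sparse vessel pixels with high blood volume and
#' CBF > 100. Geometry is a simple cylindrical slab: only the statistical
#' structure matters to the downstream analysis, not anatomy.
#'
#' Defaults encode the study regime: baseline grey-matter CBF 50 ± 8
#' mL·min⁻¹·100g⁻¹ (absolute baseline is not directly reported for this
#' model; 50 is consistent with a post-injection infarct mean near 15-20 at
#' ~40% rCBF), a ~1.5 mL spherical infarct, PET contralateral signal 100 ± 5
#' with a 4 SD defect, and affected-side oligemia at 62% of baseline, which
#' places the infarct/oligemia class separation in the discrimination regime
#' the experiment reported (per-animal AUC around 0.8).
#'
#' @param grid An [image_grid()]; default 64 x 64 x 8 pixels at 1 x 1 x 2.5 mm.
#' @param outer_radius_mm,wm_radius_mm In-plane radii (mm) of the cortical
#'   ribbon's outer edge and of the white-matter core; the grey-matter ribbon
#'   (and the hand-drawn-style cortical ROIs) lie between them.
#' @param gm_hu_mean,gm_hu_sd,wm_hu_mean,wm_hu_sd Hounsfield-unit structure
#'   of grey and white matter on the average CT image.
#' @param baseline_gm_cbf_mean,baseline_gm_cbf_sd Baseline grey-matter CBF
#'   field (mL·min⁻¹·100g⁻¹); one spatial draw per pixel, held across time.
#' @param wm_cbf_mean,wm_cbf_sd White-matter baseline CBF.
#' @param cbf_noise_sd Additive per-time-point CBF measurement noise SD.
#' @param penumbra_rcbf Fraction of baseline CBF in affected-side non-infarct
#'   grey matter (the penumbra/oligemia class); constant over time.
#' @param rcbf_timecourse Data frame with columns `time_min`,
#'   `rcbf_fraction`: the multiplicative factor applied to baseline CBF
#'   inside the infarct at each post-injection time point. Default follows
#'   the observed course: 56% at 10 and 30 min, 40% from 60 to 180 min.
#' @param infarct_radius_mm Radius of the spherical infarct; the centre sits
#'   mid-ribbon in the affected hemisphere unless `infarct_center_mm`
#'   (physical coordinates relative to the volume centre) is given.
#' @param infarct_center_mm Optional length-3 numeric, mm.
#' @param pet_contra_mean,pet_contra_sd PET uptake in normal grey matter
#'   (arbitrary activity units).
#' @param pet_defect_drop Depth of the infarct PET defect in multiples of
#'   `pet_contra_sd`; must exceed 2 so true infarct pixels fall below the
#'   mean − 2 SD detection rule with margin.
#' @param pet_wm_mean PET uptake in white matter (GABA-A receptors are
#'   predominantly cortical, so uptake is lower).
#' @param bv_gm_mean,bv_gm_sd Parenchymal blood volume (mL·100g⁻¹).
#' @param vessel_fraction Fraction of cortical-ROI pixels replaced by vessel
#'   pixels (outside the infarct).
#' @param vessel_bv_multiplier Vessel BV as a multiple of `bv_gm_mean`.
#' @param vessel_cbf Vessel CBF (set above the 100 mL·min⁻¹·100g⁻¹ cap).
#' @param noise_scale Global multiplier on every stochastic SD; 0 gives the
#'   noiseless phantom in which the segmentation rules reproduce the ground
#'   truth exactly.
#' @param infarct_present If `FALSE`, no PET defect is generated (emulating
#'   animals whose ischemia did not progress to infarction) and the
#'   ground-truth infarct mask is empty.
#' @param include_baseline_map Generate a pre-injection (time 0, fraction 1)
#'   CBF map at the head of the series. [median_cbf_map()] excludes it by
#'   default.
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration.
#' @return An object of class `phantom_config`.
#' @seealso [generate_study()], [generate_timecourse()]
#' @export
phantom_config <- function(grid = image_grid(c(64, 64, 8), c(1, 1, 2.5)),
                           outer_radius_mm = 26,
                           wm_radius_mm = 14,
                           gm_hu_mean = 45, gm_hu_sd = 1.5,
                           wm_hu_mean = 35, wm_hu_sd = 1.5,
                           baseline_gm_cbf_mean = 50, baseline_gm_cbf_sd = 8,
                           wm_cbf_mean = 25, wm_cbf_sd = 4,
                           cbf_noise_sd = 4,
                           penumbra_rcbf = 0.62,
                           rcbf_timecourse = default_rcbf_timecourse(),
                           infarct_radius_mm = 7.2,
                           infarct_center_mm = NULL,
                           pet_contra_mean = 100, pet_contra_sd = 5,
                           pet_defect_drop = 4,
                           pet_wm_mean = 60,
                           bv_gm_mean = 4, bv_gm_sd = 0.5,
                           vessel_fraction = 0.02,
                           vessel_bv_multiplier = 3,
                           vessel_cbf = 150,
                           noise_scale = 1,
                           infarct_present = TRUE,
                           include_baseline_map = TRUE,
                           seed = 1L) {
  stopifnot(inherits(grid, "image_grid"))
  tc <- as_tibble(rcbf_timecourse)
  if (!all(c("time_min", "rcbf_fraction") %in% names(tc))) {
    abort("`rcbf_timecourse` needs columns `time_min` and `rcbf_fraction`.")
  }
  if (nrow(tc) < 1L || any(diff(tc$time_min) <= 0)) {
    abort("`rcbf_timecourse` times must be strictly increasing.")
  }
  if (any(tc$rcbf_fraction <= 0 | tc$rcbf_fraction > 1.5)) {
    abort("rCBF fractions must lie in (0, 1.5].")
  }
  if (pet_defect_drop <= 2) {
    abort("`pet_defect_drop` must exceed 2 (the detection rule uses mean - 2 SD).")
  }
  if (infarct_radius_mm <= 0) abort("`infarct_radius_mm` must be positive.")
  if (wm_radius_mm <= 0 || outer_radius_mm <= wm_radius_mm) {
    abort("Need 0 < wm_radius_mm < outer_radius_mm.")
  }
  if (noise_scale < 0) abort("`noise_scale` must be >= 0.")
  if (vessel_fraction < 0 || vessel_fraction >= 1) {
    abort("`vessel_fraction` must lie in [0, 1).")
  }
  if (is.null(infarct_center_mm)) {
    infarct_center_mm <- c(-(outer_radius_mm + wm_radius_mm) / 2, 0, 0)
  }
  if (infarct_center_mm[1] + infarct_radius_mm >= 0) {
    abort("Infarct must lie entirely within the affected (x < 0) hemisphere.")
  }
  cfg <- list(
    grid = grid, outer_radius_mm = outer_radius_mm, wm_radius_mm = wm_radius_mm,
    gm_hu_mean = gm_hu_mean, gm_hu_sd = gm_hu_sd,
    wm_hu_mean = wm_hu_mean, wm_hu_sd = wm_hu_sd,
    baseline_gm_cbf_mean = baseline_gm_cbf_mean,
    baseline_gm_cbf_sd = baseline_gm_cbf_sd,
    wm_cbf_mean = wm_cbf_mean, wm_cbf_sd = wm_cbf_sd,
    cbf_noise_sd = cbf_noise_sd,
    penumbra_rcbf = penumbra_rcbf,
    rcbf_timecourse = tc,
    infarct_radius_mm = infarct_radius_mm,
    infarct_center_mm = as.numeric(infarct_center_mm),
    pet_contra_mean = pet_contra_mean, pet_contra_sd = pet_contra_sd,
    pet_defect_drop = pet_defect_drop, pet_wm_mean = pet_wm_mean,
    bv_gm_mean = bv_gm_mean, bv_gm_sd = bv_gm_sd,
    vessel_fraction = vessel_fraction,
    vessel_bv_multiplier = vessel_bv_multiplier,
    vessel_cbf = vessel_cbf,
    noise_scale = noise_scale,
    infarct_present = isTRUE(infarct_present),
    include_baseline_map = isTRUE(include_baseline_map),
    seed = as.integer(seed)
  )
  structure(cfg, class = "phantom_config")
}

#' Default infarct rCBF time course
#'
#' Post-injection CT-perfusion sampling times with the observed relative-CBF
#' trajectory of the final infarct region: 56% of baseline for the first
#' 30 minutes, then ~40% from 60 minutes to the end of the 3-hour window.
#'
#' @return Tibble with columns `time_min`, `rcbf_fraction`.
#' @export
default_rcbf_timecourse <- function() {
  tibble(
    time_min = c(10, 30, 60, 90, 120, 150, 180),
    rcbf_fraction = c(0.56, 0.56, 0.40, 0.40, 0.40, 0.40, 0.40)
  )
}

#' Infarct rCBF trajectory of a phantom configuration
#'
#' Returns the (validated) per-time-point multiplicative rCBF factor applied
#' to baseline CBF inside the infarct region.
#'
#' @param config A [phantom_config()].
#' @return Tibble with columns `time_min`, `rcbf_fraction`.
#' @export
generate_timecourse <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  config$rcbf_timecourse
}

#' Simulate on-line CBF monitoring with ET-1 re-dosing
#'
#' During the animal experiment, CBF in the ischemic territory was monitored
#' with half-hourly CT perfusion; if wear-off of the first ET-1 dose let CBF
#' rise above a target of ~20 mL·min⁻¹·100g⁻¹, a second dose was injected.
#' This helper replays that rule on a relative-CBF trajectory: at each sampled
#' time the absolute infarct-region CBF is `baseline_cbf * fraction *
#' suppression`; the first time it exceeds (strictly) `redose_threshold` an
#' event is emitted and all subsequent fractions are re-suppressed by
#' `redose_factor`. Intended for constructing realistic wear-off phantoms.
#'
#' @param timecourse Data frame with `time_min`, `rcbf_fraction`.
#' @param baseline_cbf Baseline infarct-region CBF (mL·min⁻¹·100g⁻¹).
#' @param redose_threshold Re-dose trigger (default 20); strictly-above rule.
#' @param redose_factor Multiplier applied to fractions after each event.
#' @return A list with `events` (tibble: `time_min`, `cbf_at_event`) and
#'   `effective` (tibble: `time_min`, `rcbf_fraction`, `cbf` after
#'   suppression), suitable as a replacement `rcbf_timecourse`.
#' @export
simulate_monitoring <- function(timecourse, baseline_cbf,
                                redose_threshold = 20, redose_factor = 0.5) {
  tc <- as_tibble(timecourse)
  stopifnot(all(c("time_min", "rcbf_fraction") %in% names(tc)))
  supp <- 1
  ev_t <- numeric(0)
  ev_cbf <- numeric(0)
  frac <- numeric(nrow(tc))
  cbf <- numeric(nrow(tc))
  for (i in seq_len(nrow(tc))) {
    f <- tc$rcbf_fraction[i] * supp
    v <- baseline_cbf * f
    if (v > redose_threshold) {
      ev_t <- c(ev_t, tc$time_min[i])
      ev_cbf <- c(ev_cbf, v)
      supp <- supp * redose_factor
      f <- tc$rcbf_fraction[i] * supp
      v <- baseline_cbf * f
    }
    frac[i] <- f
    cbf[i] <- v
  }
  list(
    events = tibble(time_min = ev_t, cbf_at_event = ev_cbf),
    effective = tibble(time_min = tc$time_min, rcbf_fraction = frac, cbf = cbf)
  )
}

# phantom geometry on the configured grid: logical arrays for each tissue
phantom_geometry <- function(config) {
  g <- config$grid
  n <- g$shape
  sp <- g$spacing
  xs <- ((seq_len(n[1])) - (n[1] + 1) / 2) * sp[1]
  ys <- ((seq_len(n[2])) - (n[2] + 1) / 2) * sp[2]
  zs <- ((seq_len(n[3])) - (n[3] + 1) / 2) * sp[3]
  r2 <- outer(xs^2, ys^2, "+")                      # in-plane squared radius
  brain2d <- r2 <= config$outer_radius_mm^2
  core2d <- r2 <= config$wm_radius_mm^2
  rep_slices <- function(m2d) array(rep(m2d, n[3]), dim = n)
  brain <- rep_slices(brain2d)
  wm_core <- rep_slices(core2d)
  gm <- brain & !wm_core
  left2d <- matrix(xs < 0, nrow = n[1], ncol = n[2])
  left <- rep_slices(left2d)
  cx <- config$infarct_center_mm
  d2 <- outer(outer((xs - cx[1])^2, (ys - cx[2])^2, "+"), (zs - cx[3])^2, "+")
  sphere <- d2 <= config$infarct_radius_mm^2
  list(brain = brain, wm_core = wm_core, gm = gm, affected_half = left,
       sphere = sphere)
}

#' Generate a synthetic co-registered study with known ground truth
#'
#' Builds the full multi-modal phantom described in [phantom_config()] and
#' returns both the [registered_study()] (exactly what [read_study()] would
#' produce from disk) and the ground truth needed for recovery testing.
#'
#' The ground-truth optimal CBF threshold is the value at which the infarct
#' and non-infarct median-CBF class densities cross — the population optimum
#' of Youden's J, independent of class mass. Because the per-pixel temporal
#' median of the 56%/40% time course plus noise is not exactly Gaussian, the
#' crossing is computed numerically from the generative law: a large
#' deterministic Monte-Carlo sample of class medians and a kernel-density
#' crossing between the class means.
#'
#' Generation is bit-reproducible for a given configuration (including seed);
#' the caller's RNG state is left untouched.
#'
#' @param config A [phantom_config()].
#' @return A list with elements `study` ([registered_study()]) and `truth`,
#'   a `phantom_truth` list carrying `infarct_mask`, `wm_mask`,
#'   `vessel_mask` ([roi_mask()]s), `true_infarct_cbf_mean`,
#'   `true_noninfarct_cbf_mean` and `true_optimal_threshold`
#'   (mL·min⁻¹·100g⁻¹; `NA` when `infarct_present = FALSE`).
#' @examples
#' ph <- generate_study(phantom_config(seed = 7))
#' ph$study
#' ph$truth$true_optimal_threshold
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(config$seed)

  g <- config$grid
  n <- prod(g$shape)
  ns <- config$noise_scale
  geo <- phantom_geometry(config)
  gm <- geo$gm
  wm <- geo$wm_core
  affected_gm <- gm & geo$affected_half
  contra_gm <- gm & !geo$affected_half
  infarct <- if (config$infarct_present) geo$sphere & affected_gm else
    array(FALSE, g$shape)
  penumbra <- affected_gm & !infarct

  rnorm_arr <- function(mean, sd) {
    array(stats::rnorm(n, mean, sd * ns), dim = g$shape)
  }

  # average CT image: grey ribbon over white core, air background
  hu <- array(-1000, g$shape)
  hu[gm] <- rnorm_arr(config$gm_hu_mean, config$gm_hu_sd)[gm]
  hu[wm] <- rnorm_arr(config$wm_hu_mean, config$wm_hu_sd)[wm]

  # vessels: sparse high-BV/high-CBF pixels in the cortical ribbon, never
  # inside the infarct
  candidates <- which(gm & !geo$sphere)
  n_vessel <- round(config$vessel_fraction * sum(gm))
  vessel_idx <- if (n_vessel > 0) sample(candidates, min(n_vessel, length(candidates)))
                else integer(0)
  vessel <- array(FALSE, g$shape)
  vessel[vessel_idx] <- TRUE

  # blood volume map
  bv <- array(0, g$shape)
  bv[geo$brain] <- pmax(0, rnorm_arr(config$bv_gm_mean, config$bv_gm_sd)[geo$brain])
  bv[vessel] <- pmax(0, config$vessel_bv_multiplier * config$bv_gm_mean +
                       stats::rnorm(length(vessel_idx), 0, config$bv_gm_sd * ns))

  # PET uptake: cortical signal with a defect pet_defect_drop SDs deep
  pet <- array(0, g$shape)
  pet[gm] <- rnorm_arr(config$pet_contra_mean, config$pet_contra_sd)[gm]
  pet[wm] <- rnorm_arr(config$pet_wm_mean, config$pet_contra_sd)[wm]
  if (config$infarct_present && any(infarct)) {
    defect_mean <- config$pet_contra_mean -
      config$pet_defect_drop * config$pet_contra_sd
    pet[infarct] <- stats::rnorm(sum(infarct), defect_mean,
                                 config$pet_contra_sd * ns)
  }

  # baseline CBF field, one spatial draw held across time points
  baseline <- array(0, g$shape)
  baseline[gm] <- rnorm_arr(config$baseline_gm_cbf_mean,
                            config$baseline_gm_cbf_sd)[gm]
  baseline[wm] <- rnorm_arr(config$wm_cbf_mean, config$wm_cbf_sd)[wm]
  baseline <- pmax(0, baseline)

  tc <- config$rcbf_timecourse
  times <- tc$time_min
  fracs <- tc$rcbf_fraction
  if (config$include_baseline_map) {
    times <- c(0, times)
    fracs <- c(1, fracs)
  }
  cbf_series <- vector("list", length(times))
  for (i in seq_along(times)) {
    fr <- array(1, g$shape)
    fr[penumbra] <- if (times[i] <= 0) 1 else config$penumbra_rcbf
    fr[infarct] <- fracs[i]
    v <- baseline * fr
    v[vessel] <- config$vessel_cbf
    v <- v + array(stats::rnorm(n, 0, config$cbf_noise_sd * ns), g$shape)
    cbf_series[[i]] <- scalar_map(pmax(0, v), g, "CBF", time_min = times[i])
  }

  study <- registered_study(
    cbf_series = cbf_series,
    bv_map = scalar_map(bv, g, "BV"),
    avg_image = scalar_map(hu, g, "HU"),
    pet_image = scalar_map(pet, g, "PET"),
    roi_affected = roi_mask(affected_gm, g, "affected"),
    roi_contra = roi_mask(contra_gm, g, "contralateral"),
    subject_id = sprintf("phantom-%d", config$seed)
  )

  truth <- phantom_truth(config, g, infarct, wm, geo, vessel)
  list(study = study, truth = truth)
}

# ground truth container + numeric population optimum
phantom_truth <- function(config, g, infarct, wm, geo, vessel) {
  wm_mask_arr <- wm | !geo$brain   # every structurally low-attenuation pixel
  tis <- true_class_stats(config)
  structure(
    list(
      infarct_mask = roi_mask(infarct, g),
      wm_mask = roi_mask(wm_mask_arr, g),
      vessel_mask = roi_mask(vessel, g),
      true_infarct_cbf_mean = tis$infarct_mean,
      true_noninfarct_cbf_mean = tis$noninfarct_mean,
      true_optimal_threshold = tis$crossing,
      config = config
    ),
    class = "phantom_truth"
  )
}

# Population moments of the per-pixel median CBF in each class and the
# class-density crossing (the population optimum of Youden's J), by
# deterministic Monte Carlo from the generative law (post-injection time
# points only, matching the analysis default of excluding the baseline scan
# from the median).
true_class_stats <- function(config, m = 100000L) {
  if (!config$infarct_present) {
    return(list(infarct_mean = NA_real_, noninfarct_mean = NA_real_,
                crossing = NA_real_))
  }
  set.seed(config$seed %% 1000000L + 271828L)
  ns <- config$noise_scale
  fr <- config$rcbf_timecourse$rcbf_fraction
  tn <- length(fr)
  b <- stats::rnorm(m, config$baseline_gm_cbf_mean,
                    config$baseline_gm_cbf_sd * ns)
  b <- pmax(0, b)
  med_of <- function(frac_mat) {
    v <- frac_mat * b + matrix(stats::rnorm(m * tn, 0, config$cbf_noise_sd * ns),
                               nrow = m)
    rowwise_median(pmax(v, 0))
  }
  inf_med <- med_of(matrix(fr, nrow = m, ncol = tn, byrow = TRUE))
  non_med <- med_of(matrix(config$penumbra_rcbf, nrow = m, ncol = tn))
  mu_i <- mean(inf_med)
  mu_n <- mean(non_med)
  crossing <- if (ns == 0) {
    (mu_i + mu_n) / 2   # degenerate point masses; midpoint separates them
  } else {
    youden_vertex(inf_med, non_med, mu_i, mu_n)
  }
  list(infarct_mean = mu_i, noninfarct_mean = mu_n, crossing = crossing)
}

# Population Youden optimum: the argmax of J(t) = F_low(t) - F_high(t),
# located as the vertex of a local quadratic fit to the ECDF difference
# around its grid maximum (far more stable than the raw argmax or a
# kernel-density crossing).
youden_vertex <- function(x_low, x_high, mu_low, mu_high, window = 2.5) {
  lo <- mu_low - 2 * stats::sd(x_low)
  hi <- mu_high + 2 * stats::sd(x_high)
  grid <- seq(lo, hi, by = 0.02)
  j <- stats::ecdf(x_low)(grid) - stats::ecdf(x_high)(grid)
  peak <- grid[which.max(j)]
  w <- abs(grid - peak) <= window
  if (sum(w) < 10) return(peak)
  fit <- stats::lm.fit(cbind(1, grid[w], grid[w]^2), j[w])
  a2 <- fit$coefficients[3]
  a1 <- fit$coefficients[2]
  if (!is.finite(a2) || a2 >= 0) return(peak)
  unname(-a1 / (2 * a2))
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth>\n")
  cat(sprintf("  infarct: %d px (%.2f mL); vessels: %d px; WM/background: %d px\n",
              mask_count(x$infarct_mask), mask_volume_ml(x$infarct_mask),
              mask_count(x$vessel_mask), mask_count(x$wm_mask)))
  if (is.finite(x$true_optimal_threshold %||% NA)) {
    cat(sprintf(
      "  median-CBF class means: infarct %.1f / non-infarct %.1f; optimal threshold %.1f\n",
      x$true_infarct_cbf_mean, x$true_noninfarct_cbf_mean,
      x$true_optimal_threshold))
  }
  invisible(x)
}
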