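# row-wise median of a pixels-by-timepoints matrix; non-finite entries are
# dropped per pixel. Rows that are all finite use a vectorized sort trick
# (order by row then value), the rest fall back to per-row medians.
rowwise_median <- function(x) {
  n <- nrow(x)
  tn <- ncol(x)
  if (tn == 1L) return(as.numeric(x))
  fin <- is.finite(x)
  good <- rowSums(fin) == tn
  out <- rep(NA_real_, n)
  if (any(good)) {
    xg <- x[good, , drop = FALSE]
    sorted <- matrix(xg[order(row(xg), xg)], ncol = tn, byrow = TRUE)
    if (tn %% 2L == 1L) {
      out[good] <- sorted[, (tn + 1L) %/% 2L]
    } else {
      out[good] <- (sorted[, tn %/% 2L] + sorted[, tn %/% 2L + 1L]) / 2
    }
  }
  bad <- which(!good)
  for (i in bad) {
    v <- x[i, fin[i, ]]
    out[i] <- if (length(v) > 0) stats::median(v) else NA_real_
  }
  out
}

#' Temporal median CBF map
#'
#' Reduces the serial CBF maps to one robust map by taking, at every pixel,
#' the median over the included time points. The median (rather than the
#' mean) damps the influence of transient reperfusion episodes: a pixel's
#' value is unchanged as long as fewer than half of its time points are
#' perturbed. The even-count median is the midpoint of the two central
#' values. Non-finite values are dropped per pixel, with the total dropped
#' count reported.
#'
#' The pre-injection baseline scan (any map with `time_min <= 0`) is
#' excluded by default: including a normal-flow time point in the median
#' would bias infarct CBF upward. Set `include_baseline = TRUE` to keep it.
#'
#' @param cbf_series A [registered_study()] or a list of `"CBF"`
#'   [scalar_map()]s on one grid.
#' @param include_baseline Keep maps with `time_min <= 0` (default `FALSE`).
#' @return An object of class `median_cbf_map`: a list with `map` (a `"CBF"`
#'   [scalar_map()]), `source_times`, `n_timepoints` and `n_dropped`.
#' @export
median_cbf_map <- function(cbf_series, include_baseline = FALSE) {
  if (inherits(cbf_series, "registered_study")) {
    cbf_series <- cbf_series$cbf_series
  }
  if (!is.list(cbf_series) || length(cbf_series) < 1L) {
    abort("`cbf_series` must contain at least one CBF map.")
  }
  for (m in cbf_series) {
    stopifnot(inherits(m, "scalar_map"))
    if (m$modality != "CBF") abort("All series maps must have modality \"CBF\".")
  }
  times <- vapply(cbf_series, function(m) m$time_min %||% NA_real_, numeric(1))
  keep <- if (include_baseline) rep(TRUE, length(times)) else
    (is.na(times) | times > 0)
  if (!any(keep)) {
    abort("No time points left after excluding the baseline scan.")
  }
  cbf_series <- cbf_series[keep]
  times <- times[keep]
  grid <- cbf_series[[1]]$grid
  for (m in cbf_series) {
    if (!grids_equal(m$grid, grid)) abort("Series maps must share one grid.")
  }
  x <- vapply(cbf_series, function(m) as.numeric(m$values),
              numeric(prod(grid$shape)))
  x <- matrix(x, ncol = length(cbf_series))
  n_dropped <- sum(!is.finite(x))
  if (n_dropped > 0) {
    inform(sprintf("median_cbf_map: dropped %d non-finite value(s).", n_dropped))
  }
  med <- rowwise_median(x)
  structure(
    list(
      map = scalar_map(med, grid, "CBF"),
      source_times = times,
      n_timepoints = length(cbf_series),
      n_dropped = n_dropped
    ),
    class = "median_cbf_map"
  )
}

#' @export
print.median_cbf_map <- function(x, ...) {
  cat(sprintf("<median_cbf_map> over %d time points (%s min)\n",
              x$n_timepoints, paste(x$source_times, collapse = ", ")))
  print(x$map)
  invisible(x)
}

#' Relative CBF map
#'
#' Expresses a CBF map as a percentage of the mean CBF over contralateral
#' grey matter, the conventional normalization for reporting ischemic flow
#' reduction (rCBF).
#'
#' @param cbf A `"CBF"` [scalar_map()].
#' @param contra_gm Non-empty [roi_mask()] of contralateral grey matter with
#'   positive mean CBF.
#' @return A `"CBF"` [scalar_map()] holding rCBF in percent, with attribute
#'   `contra_mean` (the normalizing mean in mL·min⁻¹·100g⁻¹).
#' @export
relative_cbf <- function(cbf, contra_gm) {
  stopifnot(inherits(cbf, "scalar_map"))
  st <- mask_stats(cbf, contra_gm)
  if (st$mean <= 0) {
    abort("Contralateral grey-matter mean CBF must be positive.")
  }
  out <- scalar_map(100 * cbf$values / st$mean, cbf$grid, "CBF",
                    time_min = cbf$time_min)
  attr(out, "contra_mean") <- st$mean
  out
}

#' Infarct-region rCBF time course
#'
#' For each CT-perfusion time point, the mean and standard error of rCBF
#' (normalized to contralateral grey matter at the same time point) over the
#' final infarct mask; plus the grand mean ± SD pooled over all time points
#' and pixels, the summary reported for the whole experiment.
#'
#' @param study A [registered_study()].
#' @param infarct_gm Non-empty [roi_mask()], the final infarct grey matter.
#' @param contra_gm Non-empty [roi_mask()] used for normalization.
#' @param include_baseline Include maps with `time_min <= 0` (default
#'   `FALSE`, matching [median_cbf_map()]).
#' @return An object of class `rcbf_timecourse`: a list with `timecourse`
#'   (tibble: `time_min`, `mean_rcbf_pct`, `se_pct`, `n_pixels`),
#'   `grand_mean_pct` and `grand_sd_pct`.
#' @export
infarct_rcbf_timecourse <- function(study, infarct_gm, contra_gm,
                                    include_baseline = FALSE) {
  stopifnot(inherits(study, "registered_study"))
  if (mask_count(infarct_gm) == 0L || mask_count(contra_gm) == 0L) {
    abort("Both masks must be non-empty.")
  }
  series <- study$cbf_series
  times <- study_times(study)
  keep <- if (include_baseline) rep(TRUE, length(times)) else times > 0
  series <- series[keep]
  times <- times[keep]
  all_vals <- numeric(0)
  rows <- lapply(seq_along(series), function(i) {
    r <- relative_cbf(series[[i]], contra_gm)
    v <- r$values[infarct_gm$members]
    v <- v[is.finite(v)]
    all_vals <<- c(all_vals, v)
    tibble(
      time_min = times[i],
      mean_rcbf_pct = mean(v),
      se_pct = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
      n_pixels = length(v)
    )
  })
  structure(
    list(
      timecourse = dplyr::bind_rows(rows),
      grand_mean_pct = mean(all_vals),
      grand_sd_pct = if (length(all_vals) > 1) stats::sd(all_vals) else 0
    ),
    class = "rcbf_timecourse"
  )
}

#' @export
print.rcbf_timecourse <- function(x, ...) {
  cat(sprintf("<rcbf_timecourse> grand mean %.1f%% (SD %.1f%%)\n",
              x$grand_mean_pct, x$grand_sd_pct))
  print(x$timecourse)
  invisible(x)
}

#' @rdname infarct_rcbf_timecourse
#' @param x An `rcbf_timecourse` object.
#' @param ... Unused.
#' @return `tidy()` returns the per-time-point tibble.
#' @export
tidy.rcbf_timecourse <- function(x, ...) x$timecourse

#' Plot an infarct rCBF time course
#'
#' Mean infarct-region rCBF against time with standard-error bars and the
#' 100% (contralateral) reference line.
#'
#' @param object An `rcbf_timecourse` from [infarct_rcbf_timecourse()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rcbf_timecourse <- function(object, ...) {
  tc <- object$timecourse
  ggplot2::ggplot(tc, ggplot2::aes(x = .data$time_min, y = .data$mean_rcbf_pct)) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_rcbf_pct - .data$se_pct,
                   ymax = .data$mean_rcbf_pct + .data$se_pct),
      width = 3
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time post injection (min)",
      y = "Infarct rCBF (% of contralateral grey matter)"
    ) +
    ggplot2::theme_minimal()
}
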