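#' Image grid geometry
#'
#' A minimal description of the voxel lattice shared by every map and mask of
#' one subject: the pixel counts along x, y, z and the physical pixel spacing
#' in millimetres. All volumes of a [registered_study()] must live on a single
#' grid; the pipeline never resamples (co-registration is assumed done
#' upstream).
#'
#' @param shape Integer vector of length 3, pixel counts `(nx, ny, nz)`; all
#'   entries must be at least 1.
#' @param spacing Numeric vector of length 3, pixel spacing `(dx, dy, dz)` in
#'   mm; all entries must be positive. Default `c(0.5, 0.5, 2.5)` follows the
#'   CT-grid convention of 2.5 mm slices when a header supplies no spacing.
#' @return An object of class `image_grid`.
#' @examples
#' image_grid(c(64, 64, 8), c(1, 1, 2.5))
#' @export
image_grid <- function(shape, spacing = c(0.5, 0.5, 2.5)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L)) {
    abort("`shape` must be three integer pixel counts, each >= 1.")
  }
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0)) {
    abort("`spacing` must be three positive pixel spacings (mm).")
  }
  structure(list(shape = shape, spacing = spacing), class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf(
    "<image_grid> %d x %d x %d pixels at %.3g x %.3g x %.3g mm\n",
    x$shape[1], x$shape[2], x$shape[3],
    x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  invisible(x)
}

#' @export
format.image_grid <- function(x, ...) {
  sprintf("%dx%dx%d @ %gx%gx%g mm", x$shape[1], x$shape[2], x$shape[3],
          x$spacing[1], x$spacing[2], x$spacing[3])
}

grids_equal <- function(a, b) {
  identical(a$shape, b$shape) && isTRUE(all.equal(a$spacing, b$spacing))
}

voxel_volume_ml <- function(grid) prod(grid$spacing) / 1000

MODALITIES <- c("CBF", "BV", "HU", "PET")

#' Scalar image volume
#'
#' One scalar value per pixel on an [image_grid()], tagged with its modality:
#' `"CBF"` (mL·min⁻¹·100g⁻¹), `"BV"` (mL·100g⁻¹), `"HU"` (Hounsfield units)
#' or `"PET"` (arbitrary activity units). CBF maps may carry the acquisition
#' time in minutes after the first endothelin-1 injection, which orders the
#' serial perfusion studies.
#'
#' Negative CBF or BV values are physically meaningless (they arise from
#' deconvolution noise upstream) and are rejected by default; with
#' `negative = "zero"` they are clamped to zero with a message.
#'
#' @param values Numeric 3-D array matching `grid$shape` (a plain vector of
#'   the right length is reshaped).
#' @param grid An [image_grid()].
#' @param modality One of `"CBF"`, `"BV"`, `"HU"`, `"PET"`.
#' @param time_min Optional acquisition time in minutes (CBF series only).
#' @param negative How to treat negative CBF/BV values: `"error"` (default)
#'   or `"zero"`.
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(values, grid, modality, time_min = NULL,
                       negative = c("error", "zero")) {
  modality <- match.arg(modality, MODALITIES)
  negative <- match.arg(negative)
  if (!inherits(grid, "image_grid")) abort("`grid` must be an image_grid.")
  values <- as.numeric(values)
  if (length(values) != prod(grid$shape)) {
    abort(sprintf(
      "`values` length %d does not match grid %s (%d pixels).",
      length(values), format(grid), prod(grid$shape)
    ))
  }
  values <- array(values, dim = grid$shape)
  if (modality %in% c("CBF", "BV")) {
    neg <- which(values < 0)
    if (length(neg) > 0) {
      if (negative == "error") {
        abort(sprintf(
          "%d negative %s pixel(s); physically invalid (use negative = \"zero\" to clamp).",
          length(neg), modality
        ))
      }
      values[neg] <- 0
      inform(sprintf("Clamped %d negative %s pixel(s) to zero.", length(neg), modality))
    }
  }
  if (!is.null(time_min)) {
    time_min <- as.numeric(time_min)
    stopifnot(length(time_min) == 1L, is.finite(time_min))
  }
  structure(
    list(values = values, grid = grid, modality = modality, time_min = time_min),
    class = "scalar_map"
  )
}

#' @export
print.scalar_map <- function(x, ...) {
  tm <- if (is.null(x$time_min)) "" else sprintf(" @ %g min", x$time_min)
  cat(sprintf("<scalar_map:%s>%s %s, range [%.3g, %.3g]\n",
              x$modality, tm, format(x$grid),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Region-of-interest mask
#'
#' A boolean membership flag per pixel on an [image_grid()], optionally tagged
#' with the hemisphere it covers (`"affected"` or `"contralateral"`). Masks
#' drive every ROI statistic and the pixel-classification rules; masks used in
#' statistics must contain at least one member pixel.
#'
#' @param members Logical 3-D array (or 0/1 numeric) matching `grid$shape`.
#' @param grid An [image_grid()].
#' @param side Optional, `"affected"` or `"contralateral"`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(members, grid, side = NULL) {
  if (!inherits(grid, "image_grid")) abort("`grid` must be an image_grid.")
  members <- array(as.logical(members), dim = grid$shape)
  if (anyNA(members)) abort("Mask membership flags may not be NA.")
  if (length(members) != prod(grid$shape)) {
    abort("Mask shape does not match grid shape.")
  }
  if (!is.null(side)) side <- match.arg(side, c("affected", "contralateral"))
  structure(list(members = members, grid = grid, side = side),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask%s> %s, %d member pixel(s) (%.2f mL)\n",
              if (is.null(x$side)) "" else paste0(":", x$side),
              format(x$grid), sum(x$members), mask_volume_ml(x)))
  invisible(x)
}

#' Number of member pixels of a mask
#' @param mask An [roi_mask()].
#' @return Integer pixel count.
#' @export
mask_count <- function(mask) sum(mask$members)

# set algebra on co-registered masks (index-aligned, no resampling)
mask_check_grids <- function(a, b) {
  if (!grids_equal(a$grid, b$grid)) {
    abort(sprintf("Masks live on different grids (%s vs %s).",
                  format(a$grid), format(b$grid)))
  }
}

#' Mask set algebra
#'
#' Index-aligned intersection, union and difference of co-registered masks.
#' The `side` tag of the first argument is kept.
#'
#' @param a,b [roi_mask()] objects on the same grid.
#' @return An [roi_mask()].
#' @export
mask_intersect <- function(a, b) {
  mask_check_grids(a, b)
  roi_mask(a$members & b$members, a$grid, a$side)
}

#' @rdname mask_intersect
#' @export
mask_union <- function(a, b) {
  mask_check_grids(a, b)
  roi_mask(a$members | b$members, a$grid, a$side)
}

#' @rdname mask_intersect
#' @export
mask_diff <- function(a, b) {
  mask_check_grids(a, b)
  roi_mask(a$members & !b$members, a$grid, a$side)
}

#' ROI summary statistics
#'
#' Mean and sample standard deviation (n − 1 denominator) of a scalar map over
#' the member pixels of a mask. These are the statistics every classification
#' rule consumes (e.g. the PET defect threshold "contralateral mean minus 2
#' SD"). Non-finite pixel values are excluded, with the excluded count
#' reported, because deconvolved perfusion maps routinely contain invalid
#' pixels. A single-pixel ROI has SD 0 by convention.
#'
#' @param map A [scalar_map()].
#' @param roi A non-empty [roi_mask()] on the same grid.
#' @return A one-row tibble with columns `mean`, `sd`, `n` (finite member
#'   pixels used) and `n_dropped` (non-finite members excluded).
#' @examples
#' g <- image_grid(c(3, 1, 1), c(1, 1, 1))
#' m <- scalar_map(c(2, 4, 6), g, "PET")
#' mask_stats(m, roi_mask(c(TRUE, TRUE, TRUE), g))
#' @export
mask_stats <- function(map, roi) {
  if (!inherits(map, "scalar_map") || !inherits(roi, "roi_mask")) {
    abort("`map` must be a scalar_map and `roi` an roi_mask.")
  }
  if (!grids_equal(map$grid, roi$grid)) {
    abort(sprintf("Map and ROI live on different grids (%s vs %s).",
                  format(map$grid), format(roi$grid)))
  }
  if (mask_count(roi) == 0L) abort("ROI is empty; statistics are undefined.")
  v <- map$values[roi$members]
  fin <- is.finite(v)
  n_dropped <- sum(!fin)
  v <- v[fin]
  if (length(v) == 0L) {
    abort("ROI contains no finite pixel values.")
  }
  if (n_dropped > 0) {
    inform(sprintf("mask_stats: excluded %d non-finite pixel(s).", n_dropped))
  }
  tibble(
    mean = mean(v),
    sd = if (length(v) > 1L) stats::sd(v) else 0,
    n = length(v),
    n_dropped = n_dropped
  )
}

#' Physical volume of a mask
#'
#' Member pixel count times the voxel volume, in millilitres. Used for the
#' grey-matter infarct volumes reported per subject.
#'
#' @param mask An [roi_mask()] with grid spacing set.
#' @return Volume in mL.
#' @examples
#' g <- image_grid(c(10, 10, 10), c(1, 1, 1))
#' mask_volume_ml(roi_mask(array(TRUE, c(10, 10, 10)), g))  # 1 mL
#' @export
mask_volume_ml <- function(mask) {
  if (!inherits(mask, "roi_mask")) abort("`mask` must be an roi_mask.")
  mask_count(mask) * voxel_volume_ml(mask$grid)
}
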