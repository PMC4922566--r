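#' Co-registered study for one subject
#'
#' Bundles everything the per-subject analysis needs, already co-registered on
#' one grid: the serial CBF maps (one per CT-perfusion time point, strictly
#' increasing acquisition times), the blood-volume map, the average
#' (perfusion-weighted) CT image in Hounsfield units, the PET uptake image,
#' and the hand-drawn cortical ROIs on the affected and contralateral sides.
#'
#' @param cbf_series List of `"CBF"` [scalar_map()]s with `time_min` set.
#' @param bv_map A `"BV"` [scalar_map()].
#' @param avg_image An `"HU"` [scalar_map()].
#' @param pet_image A `"PET"` [scalar_map()].
#' @param roi_affected,roi_contra Non-empty [roi_mask()]s.
#' @param subject_id Character identifier.
#' @return An object of class `registered_study`.
#' @export
registered_study <- function(cbf_series, bv_map, avg_image, pet_image,
                             roi_affected, roi_contra, subject_id = "subject") {
  if (!is.list(cbf_series) || length(cbf_series) < 1L) {
    abort("`cbf_series` must be a non-empty list of CBF scalar_maps.")
  }
  for (m in cbf_series) {
    if (!inherits(m, "scalar_map") || m$modality != "CBF") {
      abort("Every element of `cbf_series` must be a CBF scalar_map.")
    }
    if (is.null(m$time_min)) {
      abort("Every CBF map in the series needs `time_min` (minutes post injection).")
    }
  }
  times <- vapply(cbf_series, function(m) m$time_min, numeric(1))
  if (any(diff(times) <= 0)) {
    abort("CBF acquisition times must be strictly increasing.")
  }
  stopifnot(inherits(bv_map, "scalar_map"), bv_map$modality == "BV")
  stopifnot(inherits(avg_image, "scalar_map"), avg_image$modality == "HU")
  stopifnot(inherits(pet_image, "scalar_map"), pet_image$modality == "PET")
  stopifnot(inherits(roi_affected, "roi_mask"), inherits(roi_contra, "roi_mask"))
  grid <- bv_map$grid
  all_objs <- c(cbf_series, list(avg_image, pet_image, roi_affected, roi_contra))
  for (o in all_objs) {
    if (!grids_equal(o$grid, grid)) {
      abort(sprintf("All maps and masks must share one grid; found %s vs %s.",
                    format(o$grid), format(grid)))
    }
  }
  if (mask_count(roi_affected) == 0L || mask_count(roi_contra) == 0L) {
    abort("Both cortical ROIs must contain at least one pixel.")
  }
  structure(
    list(
      cbf_series = cbf_series, bv_map = bv_map, avg_image = avg_image,
      pet_image = pet_image, roi_affected = roi_affected,
      roi_contra = roi_contra, subject_id = as.character(subject_id),
      grid = grid
    ),
    class = "registered_study"
  )
}

#' @export
print.registered_study <- function(x, ...) {
  times <- vapply(x$cbf_series, function(m) m$time_min, numeric(1))
  cat(sprintf("<registered_study> '%s': %s\n", x$subject_id, format(x$grid)))
  cat(sprintf("  CBF series: %d time points (%s min)\n",
              length(times), paste(times, collapse = ", ")))
  cat(sprintf("  ROIs: affected %d px, contralateral %d px\n",
              mask_count(x$roi_affected), mask_count(x$roi_contra)))
  invisible(x)
}

#' CBF acquisition times of a study
#' @param study A [registered_study()].
#' @return Numeric vector of minutes post first injection.
#' @export
study_times <- function(study) {
  vapply(study$cbf_series, function(m) m$time_min, numeric(1))
}

read_manifest_file <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Manifest not found: '%s'", path))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
}

read_nifti_values <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Volume not found: '%s'", path))
  }
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3L) {
    abort(sprintf("'%s' is not a 3-D volume (dim: %s).", path,
                  paste(dm, collapse = "x")))
  }
  list(values = as.array(img), spacing = RNifti::pixdim(img)[1:3], dim = dm)
}

#' Read a co-registered study from a manifest
#'
#' The manifest (JSON or YAML, chosen by file extension) maps image roles to
#' NIfTI paths, relative to the manifest's directory unless absolute:
#'
#' ```yaml
#' subject_id: pig01
#' cbf: [{path: cbf_010.nii.gz, time_min: 10}, ...]
#' bv: bv.nii.gz
#' avg: avg.nii.gz
#' pet: pet.nii.gz
#' roi_affected: roi_aff.nii.gz     # 0/1 volume
#' roi_contra: roi_con.nii.gz
#' spacing: [1, 1, 2.5]             # optional, overrides NIfTI headers
#' ```
#'
#' All volumes must share one shape; pixel spacing is taken from the NIfTI
#' headers (first volume) unless overridden in the manifest, falling back to
#' 0.5 × 0.5 × 2.5 mm when headers carry none.
#'
#' @param manifest_path Path to the manifest file.
#' @param negative Passed to [scalar_map()]: treatment of negative CBF/BV
#'   pixels, `"error"` (default) or `"zero"`.
#' @return A validated [registered_study()].
#' @seealso [write_study()]
#' @export
read_study <- function(manifest_path, negative = c("error", "zero")) {
  negative <- match.arg(negative)
  man <- read_manifest_file(manifest_path)
  base <- dirname(normalizePath(manifest_path))
  resolve <- function(p) {
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }

  required <- c("cbf", "bv", "avg", "pet", "roi_affected", "roi_contra")
  missing <- setdiff(required, names(man))
  if (length(missing) > 0) {
    abort(sprintf("Manifest is missing required role(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (length(man$cbf) < 1L) abort("Manifest lists no CBF time points.")

  cbf_entries <- man$cbf
  first <- read_nifti_values(resolve(cbf_entries[[1]]$path))
  shape <- first$dim
  spacing <- if (!is.null(man$spacing)) {
    as.numeric(man$spacing)
  } else if (all(is.finite(first$spacing)) && all(first$spacing > 0)) {
    first$spacing
  } else {
    c(0.5, 0.5, 2.5)
  }
  grid <- image_grid(shape, spacing)

  load_vol <- function(path, role) {
    v <- read_nifti_values(resolve(path))
    if (!identical(as.integer(v$dim), grid$shape)) {
      abort(sprintf(
        "Shape mismatch for role '%s': %s is %s but the study grid is %s.",
        role, path, paste(v$dim, collapse = "x"),
        paste(grid$shape, collapse = "x")
      ))
    }
    v$values
  }

  cbf_series <- lapply(seq_along(cbf_entries), function(i) {
    e <- cbf_entries[[i]]
    if (is.null(e$path) || is.null(e$time_min)) {
      abort("Each cbf entry needs `path` and `time_min`.")
    }
    vals <- if (i == 1L) first$values else load_vol(e$path, sprintf("cbf[%d]", i))
    scalar_map(vals, grid, "CBF", time_min = e$time_min, negative = negative)
  })

  mask_from <- function(path, role, side) {
    m <- roi_mask(load_vol(path, role) > 0.5, grid, side)
    if (mask_count(m) == 0L) {
      abort(sprintf("ROI '%s' is empty.", role))
    }
    m
  }

  registered_study(
    cbf_series = cbf_series,
    bv_map = scalar_map(load_vol(man$bv, "bv"), grid, "BV", negative = negative),
    avg_image = scalar_map(load_vol(man$avg, "avg"), grid, "HU"),
    pet_image = scalar_map(load_vol(man$pet, "pet"), grid, "PET"),
    roi_affected = mask_from(man$roi_affected, "roi_affected", "affected"),
    roi_contra = mask_from(man$roi_contra, "roi_contra", "contralateral"),
    subject_id = man$subject_id %||% "subject"
  )
}

write_nifti_volume <- function(values, grid, path) {
  arr <- array(as.numeric(values), dim = grid$shape)
  attr(arr, "pixdim") <- grid$spacing
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a study to disk as NIfTI volumes plus a manifest
#'
#' Inverse of [read_study()]: writes each volume as `.nii.gz` (masks as 0/1
#' volumes) into `dir` and a `manifest.json` referencing them, so that
#' `read_study(file.path(dir, "manifest.json"))` round-trips the study.
#'
#' @param study A [registered_study()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "registered_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- study$grid
  cbf <- lapply(study$cbf_series, function(m) {
    fn <- sprintf("cbf_t%03d.nii.gz", round(m$time_min))
    write_nifti_volume(m$values, g, file.path(dir, fn))
    list(path = fn, time_min = m$time_min)
  })
  write_nifti_volume(study$bv_map$values, g, file.path(dir, "bv.nii.gz"))
  write_nifti_volume(study$avg_image$values, g, file.path(dir, "avg.nii.gz"))
  write_nifti_volume(study$pet_image$values, g, file.path(dir, "pet.nii.gz"))
  write_nifti_volume(study$roi_affected$members * 1, g,
                     file.path(dir, "roi_affected.nii.gz"))
  write_nifti_volume(study$roi_contra$members * 1, g,
                     file.path(dir, "roi_contra.nii.gz"))
  man <- list(
    subject_id = study$subject_id,
    spacing = g$spacing,
    cbf = cbf,
    bv = "bv.nii.gz", avg = "avg.nii.gz", pet = "pet.nii.gz",
    roi_affected = "roi_affected.nii.gz", roi_contra = "roi_contra.nii.gz"
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
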