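#' DWI series container
#'
#' Bundles one 3D signal volume per diffusion weighting (b-value) together
#' with the voxel spacing. All volumes must be co-registered on one grid.
#'
#' @param volumes List of 3D numeric arrays (one per b-value), identical
#'   dimensions, non-negative signal.
#' @param b_values Numeric vector of diffusion weightings in s/mm^2, one per
#'   volume; at least two must be distinct.
#' @param voxel_spacing_mm Numeric length-3, per-axis voxel spacing in mm.
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(volumes, b_values, voxel_spacing_mm) {
  stopifnot(is.list(volumes), length(volumes) == length(b_values))
  if (length(unique(b_values)) < 2) {
    stop("a DWI series needs at least two distinct b-values", call. = FALSE)
  }
  dims <- lapply(volumes, dim)
  if (any(vapply(dims, length, 1L) != 3L)) {
    stop("all volumes must be 3D arrays", call. = FALSE)
  }
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("all volumes must share one grid shape", call. = FALSE)
  }
  check_spacing(voxel_spacing_mm)
  structure(
    list(volumes = volumes, b_values = as.numeric(b_values),
         voxel_spacing_mm = as.numeric(voxel_spacing_mm)),
    class = "dwi_series"
  )
}

#' ADC map container
#'
#' @param values 3D numeric array of apparent diffusion coefficients in
#'   mm^2/s; `NA` marks voxels where the fit is undefined.
#' @param voxel_spacing_mm Numeric length-3 voxel spacing in mm.
#' @return An object of class `adc_map`.
#' @export
adc_map <- function(values, voxel_spacing_mm) {
  stopifnot(length(dim(values)) == 3L)
  check_spacing(voxel_spacing_mm)
  structure(list(values = values, voxel_spacing_mm = as.numeric(voxel_spacing_mm)),
            class = "adc_map")
}

#' Tumor ROI mask container
#'
#' @param mask 3D logical array; `TRUE` marks in-tumor voxels. At least one
#'   voxel must be `TRUE`.
#' @param voxel_spacing_mm Numeric length-3 voxel spacing in mm.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, voxel_spacing_mm) {
  stopifnot(length(dim(mask)) == 3L)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  if (!any(mask)) stop("ROI mask is empty: no voxel is TRUE", call. = FALSE)
  check_spacing(voxel_spacing_mm)
  structure(list(mask = mask, voxel_spacing_mm = as.numeric(voxel_spacing_mm)),
            class = "roi_mask")
}

check_spacing <- function(sp) {
  if (length(sp) != 3L || !is.numeric(sp) || any(!is.finite(sp)) || any(sp <= 0)) {
    stop("voxel_spacing_mm must be three positive numbers", call. = FALSE)
  }
  invisible(sp)
}

check_same_grid <- function(a, b) {
  da <- dim(if (!is.null(a$values)) a$values else if (!is.null(a$mask)) a$mask else a$volumes[[1]])
  db <- dim(if (!is.null(b$values)) b$values else if (!is.null(b$mask)) b$mask else b$volumes[[1]])
  if (!identical(da, db)) stop("grids do not match: ", paste(da, collapse = "x"),
                               " vs ", paste(db, collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.dwi_series <- function(x, ...) {
  cat("<dwi_series> ", paste(dim(x$volumes[[1]]), collapse = " x "),
      " voxels, b = ", paste(x$b_values, collapse = "/"),
      " s/mm^2, spacing ", paste(x$voxel_spacing_mm, collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' @export
print.adc_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat("<adc_map> ", paste(dim(x$values), collapse = " x "),
      " voxels, defined ", length(v), ", median ",
      if (length(v)) signif(stats::median(v), 4) else NA, " mm^2/s\n", sep = "")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", paste(dim(x$mask), collapse = " x "), " voxels, ",
      sum(x$mask), " in ROI\n", sep = "")
  invisible(x)
}
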