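#' Fit an ADC map from a multi-b-value DWI series
#'
#' Computes the apparent diffusion coefficient voxelwise as minus the slope of
#' the least-squares line of log signal against b, using every b-value whose
#' signal is strictly positive at that voxel. This is the standard log-linear
#' reading of mono-exponential signal decay S(b) = S0 exp(-b ADC): with
#' noiseless three-point decay the generating coefficient is recovered to
#' machine precision.
#'
#' Voxels with fewer than two positive signals are set to `NA` (undefined) and
#' excluded downstream rather than raising an error, since background and
#' fully-attenuated voxels are expected in magnitude MRI. Negative fitted
#' slopes (signal increasing with b, possible under noise) are clamped to an
#' ADC of 0 by default so that downstream statistics never see negative
#' diffusivity.
#'
#' @param series A [dwi_series()].
#' @param clamp_negative Clamp negative fitted ADC values to 0 (default
#'   `TRUE`); set `FALSE` to keep the raw slope.
#' @return An [adc_map()] on the same grid, in mm^2/s.
#' @examples
#' s0 <- 1000; d <- 2e-3; b <- c(0, 400, 800)
#' vols <- lapply(b, function(bb) array(s0 * exp(-bb * d), c(2, 2, 1)))
#' fit_adc(dwi_series(vols, b, c(1, 1, 1)))$values[1, 1, 1]
#' @export
fit_adc <- function(series, clamp_negative = TRUE) {
  stopifnot(inherits(series, "dwi_series"))
  b <- series$b_values
  dims <- dim(series$volumes[[1]])
  nvox <- prod(dims)
  nb <- length(b)
  s <- matrix(vapply(series$volumes, as.numeric, numeric(nvox)),
              nrow = nvox, ncol = nb)
  if (any(s < 0, na.rm = TRUE)) stop("DWI signals must be non-negative", call. = FALSE)
  y <- suppressWarnings(log(s))
  y[!is.finite(y)] <- NA_real_
  use <- !is.na(y)
  k <- rowSums(use)
  bm <- matrix(b, nvox, nb, byrow = TRUE)
  bm[!use] <- NA_real_
  bbar <- rowMeans(bm, na.rm = TRUE)
  ybar <- rowMeans(y, na.rm = TRUE)
  sxy <- rowSums((bm - bbar) * (y - ybar), na.rm = TRUE)
  sxx <- rowSums((bm - bbar)^2, na.rm = TRUE)
  adc <- -sxy / sxx
  adc[k < 2 | sxx == 0] <- NA_real_
  if (clamp_negative) adc <- pmax(adc, 0)
  adc_map(array(adc, dims), series$voxel_spacing_mm)
}

#' Tumor volume from an ROI mask
#'
#' Volume is the number of in-ROI voxels multiplied by the unit voxel volume,
#' converted from mm^3 to cm^3.
#'
#' @param mask A [roi_mask()].
#' @return Tumor volume in cm^3.
#' @examples
#' m <- array(TRUE, c(10, 10, 10))
#' tumor_volume(roi_mask(m, c(1, 1, 1)))  # 1 cm^3
#' @export
tumor_volume <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  sum(mask$mask) * prod(mask$voxel_spacing_mm) / 1000
}
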