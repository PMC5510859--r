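#' Plot an axial ADC slice
#'
#' @param adc An [adc_map()].
#' @param mask Optional [roi_mask()]; when given, the ROI outline values are
#'   shown and background voxels are blanked.
#' @param slice Slice index along z (default: the slice with the most ROI
#'   voxels, or the middle slice without a mask).
#' @return A ggplot object.
#' @export
plot_adc_slice <- function(adc, mask = NULL, slice = NULL) {
  stopifnot(inherits(adc, "adc_map"))
  if (is.null(slice)) {
    slice <- if (!is.null(mask)) which.max(apply(mask$mask, 3, sum))
             else ceiling(dim(adc$values)[3] / 2)
  }
  v <- adc$values[, , slice]
  if (!is.null(mask)) v[!mask$mask[, , slice]] <- NA
  df <- expand.grid(x = seq_len(nrow(v)), y = seq_len(ncol(v)))
  df$adc <- as.vector(v)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$adc)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20", name = "ADC\n(mm²/s)") +
    ggplot2::coord_fixed(ratio = adc$voxel_spacing_mm[2] / adc$voxel_spacing_mm[1]) +
    ggplot2::labs(title = paste0("ADC map, slice ", slice), x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_adc_slice Plot a quantized (discrete grey-level) slice.
#' @param q A [quantize()]d ROI.
#' @export
plot_discrete_slice <- function(q, slice = NULL) {
  stopifnot(inherits(q, "quantized_roi"))
  if (is.null(slice)) slice <- which.max(apply(!is.na(q$levels), 3, sum))
  v <- q$levels[, , slice]
  df <- expand.grid(x = seq_len(nrow(v)), y = seq_len(ncol(v)))
  df$level <- as.vector(v)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$level)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20", name = "level",
                                  limits = c(1, q$n_levels)) +
    ggplot2::coord_fixed(ratio = q$voxel_spacing_mm[2] / q$voxel_spacing_mm[1]) +
    ggplot2::labs(title = paste0("Discrete map (1..", q$n_levels, "), slice ", slice),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.glcm <- function(object, trans = "log10", ...) {
  p <- object$p
  df <- expand.grid(i = seq_len(nrow(p)), j = seq_len(ncol(p)))
  df$p <- as.vector(p)
  df$p[df$p == 0] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans, na.value = "grey95",
                                  name = "p(i,j)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Grey-level co-occurrence matrix",
                  x = "grey level i", y = "grey level j") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.glszm <- function(object, ...) {
  ggplot2::ggplot(object$zones,
                  ggplot2::aes(x = .data$size, y = .data$level,
                               fill = .data$n_zones)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "zones") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(title = "Grey-level size-zone matrix",
                  x = "zone size (voxels)", y = "grey level") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.myxtex_roc <- function(object, ...) {
  df <- tidy.myxtex_roc(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("ROC curve (AUC = %.3f)", object$auc),
                  x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Feature distributions by group
#'
#' Jittered strip plot of each texture feature by group, free y scales.
#'
#' @param features Cohort feature tibble (with a `group` column).
#' @param feature_cols Features to show (default: all texture features
#'   present).
#' @return A ggplot object.
#' @export
plot_features <- function(features, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- intersect(texture_feature_names(), names(features))
  }
  long <- tidyr::pivot_longer(features[, c("group", feature_cols)],
                              -"group", names_to = "feature")
  long$feature <- factor(long$feature, levels = feature_cols)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7, show.legend = FALSE) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          show.legend = FALSE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
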