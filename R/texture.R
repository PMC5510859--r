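#' Histogram (global) features of the in-ROI ADC distribution
#'
#' First four moments of the voxelwise ADC histogram: arithmetic mean, sample
#' SD (n - 1 denominator), skewness `m3 / m2^1.5` and non-excess kurtosis
#' `m4 / m2^2` (Gaussian = 3), with `mr` the r-th central population moment.
#' For a constant ROI, skewness and kurtosis are undefined and returned as
#' `NA`.
#'
#' @param adc An [adc_map()].
#' @param mask A [roi_mask()] on the same grid.
#' @return A one-row tibble with columns `mean`, `sd`, `skewness`, `kurtosis`.
#' @export
global_features <- function(adc, mask) {
  stopifnot(inherits(adc, "adc_map"), inherits(mask, "roi_mask"))
  check_same_grid(adc, mask)
  x <- adc$values[mask$mask]
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least two defined ROI voxels", call. = FALSE)
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 == 0) {
    return(tibble::tibble(mean = m, sd = 0, skewness = NA_real_, kurtosis = NA_real_))
  }
  tibble::tibble(
    mean = m,
    sd = stats::sd(x),
    skewness = mean(d^3) / m2^1.5,
    kurtosis = mean(d^4) / m2^2
  )
}

#' Quantize in-ROI ADC values to discrete grey levels
#'
#' Equal-width binning of the per-ROI `[min, max]` ADC range into `levels`
#' bins: `level = 1 + floor(levels * (x - min) / (max - min))`, with the
#' maximum clamped to the top level. A constant ROI maps entirely to level 1.
#' Voxels outside the ROI (or with undefined ADC) carry no level (`NA`).
#'
#' @param adc An [adc_map()].
#' @param mask A [roi_mask()] on the same grid.
#' @param levels Number of grey levels (default 64, i.e. values 1..64).
#' @return A `quantized_roi` object: integer `levels` array (`NA` outside the
#'   ROI), level count `n_levels`, and the `adc_range` used for binning.
#' @export
quantize <- function(adc, mask, levels = 64L) {
  stopifnot(inherits(adc, "adc_map"), inherits(mask, "roi_mask"), levels >= 1)
  check_same_grid(adc, mask)
  inroi <- mask$mask & is.finite(adc$values)
  if (!any(inroi)) stop("no defined ADC voxel inside the ROI", call. = FALSE)
  x <- adc$values[inroi]
  mn <- min(x); mx <- max(x)
  lev <- array(NA_integer_, dim(adc$values))
  if (mx == mn) {
    lev[inroi] <- 1L
  } else {
    l <- 1L + as.integer(floor(levels * (x - mn) / (mx - mn)))
    l[l > levels] <- as.integer(levels)  # x == max
    lev[inroi] <- l
  }
  structure(list(levels = lev, n_levels = as.integer(levels),
                 adc_range = c(mn, mx),
                 voxel_spacing_mm = adc$voxel_spacing_mm),
            class = "quantized_roi")
}

# The 13 unique 3D offsets at 1-voxel (Chebyshev) distance: the
# 26-neighbourhood modulo sign.
glcm_offsets <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0),
        c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

# Aligned subarrays of `arr` at lag `off` (index space); NULL if the offset
# exceeds the grid.
shifted_pair <- function(arr, off) {
  d <- dim(arr)
  src <- vector("list", 3)
  for (k in 1:3) {
    o <- off[k]
    n_valid <- d[k] - abs(o)
    if (n_valid < 1) return(NULL)
    src[[k]] <- if (o >= 0) seq_len(n_valid) else seq_len(n_valid) + abs(o)
  }
  list(a = arr[src[[1]], src[[2]], src[[3]], drop = FALSE],
       b = arr[src[[1]] + off[1], src[[2]] + off[2], src[[3]] + off[3], drop = FALSE])
}

#' Rotation-invariant grey-level co-occurrence matrix
#'
#' For each of the 13 unique 3D offsets at a 1-voxel distance (the
#' 26-neighbourhood modulo sign), counts ordered grey-level pairs whose two
#' voxels both lie in the ROI, symmetrizes (adds the transpose), normalizes
#' each directional matrix to sum 1, and averages the directional matrices.
#' Directions contributing no valid pair are skipped and the average is taken
#' over the remaining directions. Offsets are measured in index space, so
#' voxel anisotropy is ignored, matching the 1-voxel-distance convention.
#'
#' @param q A [quantize()]d ROI.
#' @param distance Offset magnitude in voxels (default 1).
#' @return A `glcm` object: probability matrix `p` (`n_levels` square,
#'   symmetric, sums to 1), `n_directions` averaged, and `distance`.
#' @export
compute_glcm <- function(q, distance = 1L) {
  stopifnot(inherits(q, "quantized_roi"), distance >= 1)
  L <- q$n_levels
  offs <- glcm_offsets() * as.integer(distance)
  acc <- matrix(0, L, L)
  used <- 0L
  for (i in seq_len(nrow(offs))) {
    sp <- shifted_pair(q$levels, offs[i, ])
    if (is.null(sp)) next
    ok <- !is.na(sp$a) & !is.na(sp$b)
    if (!any(ok)) next
    counts <- tabulate((sp$a[ok] - 1L) * L + sp$b[ok], nbins = L * L)
    cmat <- matrix(counts, L, L, byrow = TRUE)
    cmat <- cmat + t(cmat)
    acc <- acc + cmat / sum(cmat)
    used <- used + 1L
  }
  if (used == 0L) {
    stop("no in-ROI voxel pair at the requested distance in any direction", call. = FALSE)
  }
  structure(list(p = acc / used, n_directions = used,
                 distance = as.integer(distance), n_levels = L),
            class = "glcm")
}

#' Grey-level size-zone matrix
#'
#' Zones are maximal connected components of equal grey level restricted to
#' the ROI; `M(m, n)` counts zones of level `m` and size `n` voxels.
#' Connectivity is 26 (faces, edges and corners) by default, the common
#' radiomics convention; 6 (faces only) is available.
#'
#' @param q A [quantize()]d ROI.
#' @param connectivity Zone connectivity, 26 or 6.
#' @return A `glszm` object: tibble `zones` with columns `level`, `size`,
#'   `n_zones`; total zone count `n_zones`; ROI voxel count `n_voxels`.
#' @export
compute_glszm <- function(q, connectivity = 26L) {
  stopifnot(inherits(q, "quantized_roi"))
  connectivity <- match.arg(as.character(connectivity), c("26", "6"))
  offs <- if (connectivity == "26") glcm_offsets() else glcm_offsets()[1:3, , drop = FALSE]
  lev <- q$levels
  roi_lin <- which(!is.na(lev))
  n_roi <- length(roi_lin)
  rank <- rep(NA_integer_, length(lev))
  rank[roi_lin] <- seq_len(n_roi)
  idx <- array(seq_along(lev), dim(lev))
  efrom <- eto <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    sl <- shifted_pair(lev, offs[i, ])
    if (is.null(sl)) next
    si <- shifted_pair(idx, offs[i, ])
    ok <- !is.na(sl$a) & !is.na(sl$b) & sl$a == sl$b
    if (!any(ok)) next
    efrom[[i]] <- rank[si$a[ok]]
    eto[[i]] <- rank[si$b[ok]]
  }
  ef <- unlist(efrom); et <- unlist(eto)
  if (length(ef)) {
    g <- igraph::make_graph(edges = rbind(ef, et), n = n_roi, directed = FALSE)
    comp <- igraph::components(g)
    membership <- comp$membership
    sizes <- comp$csize
  } else {
    membership <- seq_len(n_roi)
    sizes <- rep(1L, n_roi)
  }
  lev_roi <- lev[roi_lin]
  comp_level <- lev_roi[match(seq_along(sizes), membership)]
  zones <- dplyr::count(
    tibble::tibble(level = comp_level, size = as.integer(sizes)),
    .data$level, .data$size, name = "n_zones"
  )
  structure(list(zones = zones, n_zones = length(sizes),
                 n_voxels = n_roi, n_levels = q$n_levels,
                 connectivity = as.integer(connectivity)),
            class = "glszm")
}

#' Dense matrix view of a GLSZM
#'
#' @param z A [compute_glszm()] result.
#' @return An integer matrix with `n_levels` rows (grey level) and `max size`
#'   columns (zone size), entries = zone counts.
#' @export
glszm_matrix <- function(z) {
  stopifnot(inherits(z, "glszm"))
  m <- matrix(0L, z$n_levels, max(z$zones$size))
  m[cbind(z$zones$level, z$zones$size)] <- z$zones$n_zones
  dimnames(m) <- list(level = seq_len(nrow(m)), size = seq_len(ncol(m)))
  m
}

#' Regional (GLSZM) features
#'
#' Intensity variability `(1/NZ) * sum_m (sum_n M(m,n))^2` emphasizes the
#' grey-level rows of the size-zone matrix; size-zone variability
#' `(1/NZ) * sum_n (sum_m M(m,n))^2` emphasizes the zone-size columns. Both
#' have a floor of 1 (a single zone) and scale linearly when every zone is
#' duplicated; size-zone variability grows with the voxel count of the ROI.
#'
#' @param z A [compute_glszm()] result.
#' @return A one-row tibble with columns `intensity_variability` and
#'   `size_zone_variability`.
#' @export
glszm_features <- function(z) {
  stopifnot(inherits(z, "glszm"), z$n_zones >= 1)
  by_level <- tapply(z$zones$n_zones, z$zones$level, sum)
  by_size <- tapply(z$zones$n_zones, z$zones$size, sum)
  tibble::tibble(
    intensity_variability = sum(by_level^2) / z$n_zones,
    size_zone_variability = sum(by_size^2) / z$n_zones
  )
}

#' Local (GLCM, Haralick) features
#'
#' With `p(i, j)` the co-occurrence probabilities, marginal
#' `px(i) = sum_j p(i, j)`, `mu = sum_i i px(i)` and
#' `sigma2 = sum_i (i - mu)^2 px(i)`:
#' energy `sum p^2`; entropy `-sum p log p` (0 log 0 := 0; natural log by
#' default, base 2 selectable); correlation
#' `(sum_ij i j p(i,j) - mu^2) / sigma2` (`NA` when a single level is
#' occupied); contrast `sum (i-j)^2 p`; homogeneity `sum p / (1 + |i-j|)`;
#' variance `sum_ij (i - mu)^2 p(i, j)`; maximum probability `max p`.
#'
#' @param g A [compute_glcm()] result.
#' @param log_base Logarithm base for entropy (default `exp(1)`).
#' @return A one-row tibble with columns `energy`, `entropy`, `correlation`,
#'   `contrast`, `homogeneity`, `variance`, `max_probability`.
#' @export
glcm_features <- function(g, log_base = exp(1)) {
  stopifnot(inherits(g, "glcm"))
  p <- g$p
  L <- nrow(p)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(seq_len(L) * px)
  sigma2 <- sum((seq_len(L) - mu)^2 * px)
  pos <- p > 0
  corr <- if (sigma2 == 0) NA_real_ else (sum(i * j * p) - mu^2) / sigma2
  tibble::tibble(
    energy = sum(p^2),
    entropy = -sum(p[pos] * log(p[pos], base = log_base)),
    correlation = corr,
    contrast = sum((i - j)^2 * p),
    homogeneity = sum(p / (1 + abs(i - j))),
    variance = sum((i - mu)^2 * p),
    max_probability = max(p)
  )
}

#' Extract the full texture feature vector for one subject
#'
#' Runs the complete per-subject feature pipeline on an ADC map and tumor
#' mask: global histogram features on the raw ADC values, then 64-level
#' quantization feeding the GLSZM (regional) and 13-direction GLCM (local)
#' features, plus the tumor volume.
#'
#' @param adc An [adc_map()].
#' @param mask A [roi_mask()] on the same grid.
#' @param levels Grey-level count for quantization (default 64).
#' @param connectivity GLSZM zone connectivity (26 or 6).
#' @param log_base Entropy logarithm base.
#' @return A one-row tibble with the 13 named texture features plus
#'   `volume_cm3`.
#' @export
extract_features <- function(adc, mask, levels = 64L, connectivity = 26L,
                             log_base = exp(1)) {
  q <- quantize(adc, mask, levels)
  dplyr::bind_cols(
    global_features(adc, mask),
    glszm_features(compute_glszm(q, connectivity)),
    glcm_features(compute_glcm(q), log_base = log_base),
    tibble::tibble(volume_cm3 = tumor_volume(mask))
  )
}

#' Names of the thirteen texture features
#'
#' @param with_volume Append `volume_cm3`.
#' @return Character vector of feature column names in table order.
#' @export
texture_feature_names <- function(with_volume = FALSE) {
  nm <- c("mean", "sd", "skewness", "kurtosis",
          "intensity_variability", "size_zone_variability",
          "energy", "entropy", "correlation", "contrast", "homogeneity",
          "variance", "max_probability")
  if (with_volume) c(nm, "volume_cm3") else nm
}

#' @export
print.glcm <- function(x, ...) {
  cat("<glcm> ", x$n_levels, " levels, ", x$n_directions,
      " directions averaged, distance ", x$distance, " voxel\n", sep = "")
  invisible(x)
}

#' @export
print.glszm <- function(x, ...) {
  cat("<glszm> ", x$n_zones, " zones over ", x$n_voxels, " ROI voxels (",
      x$connectivity, "-connectivity)\n", sep = "")
  invisible(x)
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat("<quantized_roi> ", sum(!is.na(x$levels)), " voxels at ", x$n_levels,
      " levels, ADC range [", signif(x$adc_range[1], 4), ", ",
      signif(x$adc_range[2], 4), "]\n", sep = "")
  invisible(x)
}
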