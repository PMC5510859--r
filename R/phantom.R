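#' Specify a single synthetic tumor phantom
#'
#' A phantom is an ellipsoidal tumor embedded in an empty background. Its true
#' ADC field follows one of two spatial archetypes motivated by the histology
#' of myxoid-containing soft-tissue tumors:
#'
#' * `"benign"` (heterogeneous): a concentric two-compartment field with a
#'   low-ADC fibrous-like core occupying `core_fraction` of the ellipsoid
#'   radius and a high-ADC myxoid-like rim, plus a short-correlation jitter
#'   field that makes the texture spatially rough.
#' * `"malignant"` (homogeneous): a single-compartment field `adc_uniform`
#'   modulated only by a smooth (long-correlation) jitter field, i.e. wide but
#'   slowly-varying diffusivity.
#'
#' DWI signal for each b-value is `s0_signal * exp(-b * ADC)` inside the
#' tumor and 0 outside, corrupted by Rician noise of SD `s0_signal / snr`
#' (magnitude MRI noise; reduces to the noise-free magnitude as `snr` tends to
#' infinity). Noise is drawn independently per b-value volume, as for separate
#' acquisitions.
#'
#' @param tumor_class `"benign"` or `"malignant"` spatial archetype.
#' @param tumor_semiaxes_mm Ellipsoid semi-axes (x, y, z) in mm.
#' @param voxel_spacing_mm Per-axis voxel spacing in mm.
#' @param grid_shape Integer voxel counts per axis, or `NULL` to size the grid
#'   to the ellipsoid plus a 2-voxel margin.
#' @param core_fraction Fraction (0..1) of the ellipsoid radius occupied by
#'   the low-ADC core (benign class only). The default 0.794 puts half the
#'   tumor volume in each compartment (0.794^3 = 0.5).
#' @param adc_core,adc_rim Core/rim diffusion coefficients in mm^2/s (benign).
#' @param adc_uniform Diffusion coefficient in mm^2/s (malignant).
#' @param adc_jitter_sd SD of the spatial ADC jitter field, mm^2/s. Default
#'   0.22e-3 (benign) or 0.33e-3 (malignant), giving both classes a broadly
#'   similar marginal spread once the benign core-rim gap is included.
#' @param jitter_smooth_mm Gaussian correlation length (kernel SD, mm) of the
#'   jitter field; 0 gives voxelwise white jitter. Default 1 mm (benign:
#'   spatially rough texture) or 8 mm (malignant: slowly varying diffusivity).
#'   This is the knob that separates the classes' spatial arrangement while
#'   leaving their marginal distributions similar.
#' @param s0_signal Baseline (b = 0) signal magnitude.
#' @param snr Ratio of `s0_signal` to the noise SD; `Inf` disables noise.
#' @param b_values Diffusion weightings in s/mm^2.
#' @param seed Integer RNG seed; identical spec + seed gives identical output.
#' @return A `phantom_spec` list.
#' @seealso [make_phantom()], [cohort_spec()]
#' @export
phantom_spec <- function(tumor_class = c("benign", "malignant"),
                         tumor_semiaxes_mm = c(15, 12, 10.5),
                         voxel_spacing_mm = c(1.25, 1.25, 5),
                         grid_shape = NULL,
                         core_fraction = 0.794,
                         adc_core = 1.40e-3,
                         adc_rim = 2.70e-3,
                         adc_uniform = 1.914e-3,
                         adc_jitter_sd = NULL,
                         jitter_smooth_mm = NULL,
                         s0_signal = 1000,
                         snr = 60,
                         b_values = c(0, 400, 800),
                         seed = 1L) {
  tumor_class <- match.arg(tumor_class)
  if (is.null(adc_jitter_sd)) {
    adc_jitter_sd <- if (tumor_class == "benign") 0.22e-3 else 0.33e-3
  }
  if (is.null(jitter_smooth_mm)) {
    jitter_smooth_mm <- if (tumor_class == "benign") 1 else 8
  }
  check_spacing(voxel_spacing_mm)
  stopifnot(length(tumor_semiaxes_mm) == 3, all(tumor_semiaxes_mm > 0))
  for (nm in c("adc_core", "adc_rim", "adc_uniform")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0 || v >= 4e-3) {
      stop(nm, " must lie in (0, 4e-3) mm^2/s (free-water physical bound)", call. = FALSE)
    }
  }
  if (adc_jitter_sd < 0 || adc_jitter_sd >= 4e-3) {
    stop("adc_jitter_sd must lie in [0, 4e-3) mm^2/s", call. = FALSE)
  }
  if (core_fraction < 0 || core_fraction > 1) {
    stop("core_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!(snr > 0)) stop("snr must be positive", call. = FALSE)
  if (s0_signal <= 0) stop("s0_signal must be positive", call. = FALSE)
  if (!is.null(grid_shape)) {
    stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
    grid_shape <- as.integer(grid_shape)
  }
  structure(list(
    tumor_class = tumor_class, tumor_semiaxes_mm = as.numeric(tumor_semiaxes_mm),
    voxel_spacing_mm = as.numeric(voxel_spacing_mm), grid_shape = grid_shape,
    core_fraction = core_fraction, adc_core = adc_core, adc_rim = adc_rim,
    adc_uniform = adc_uniform, adc_jitter_sd = adc_jitter_sd,
    jitter_smooth_mm = jitter_smooth_mm, s0_signal = s0_signal, snr = snr,
    b_values = as.numeric(b_values), seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Generate a synthetic DWI phantom
#'
#' Materialises a [phantom_spec()]: builds the ellipsoid ROI mask, draws the
#' true ADC field (two-compartment or uniform plus spatially correlated
#' Gaussian jitter, clamped to the physical range (0, 4e-3] mm^2/s), and
#' simulates one Rician-noised magnitude volume per b-value.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `dwi` ([dwi_series()]), `mask` ([roi_mask()])
#'   and `true_adc` ([adc_map()]; `NA` outside the tumor).
#' @examples
#' ph <- make_phantom(phantom_spec("malignant", snr = Inf, adc_jitter_sd = 0))
#' range(ph$true_adc$values, na.rm = TRUE)
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$voxel_spacing_mm
  ax <- spec$tumor_semiaxes_mm
  dims <- spec$grid_shape
  if (is.null(dims)) dims <- as.integer(ceiling(2 * ax / sp) + 4L)
  half_extent <- dims * sp / 2
  over <- which(ax > half_extent - sp)  # need >= 1 voxel clearance
  if (length(over)) {
    stop("ellipsoid does not fit inside the grid along axis ",
         paste(c("x", "y", "z")[over], collapse = ", "), call. = FALSE)
  }
  coords <- lapply(1:3, function(k) (seq_len(dims[k]) - (dims[k] + 1) / 2) * sp[k])
  # normalised elliptic radius on the full grid
  r1 <- (coords[[1]] / ax[1])^2
  r2 <- (coords[[2]] / ax[2])^2
  r3 <- (coords[[3]] / ax[3])^2
  rho2 <- outer(outer(r1, r2, `+`), r3, `+`)
  mask <- rho2 <= 1
  if (!any(mask)) stop("ellipsoid contains no voxel at this spacing", call. = FALSE)

  withr::with_seed(spec$seed, {
    if (spec$adc_jitter_sd > 0) {
      jitter <- stats::rnorm(prod(dims))
      dim(jitter) <- dims
      if (spec$jitter_smooth_mm > 0) {
        jitter <- smooth_field(jitter, spec$jitter_smooth_mm / sp)
      }
      jitter <- jitter - mean(jitter)  # pure fluctuation; level is set by the base field
      sj <- stats::sd(jitter)
      jitter <- if (sj > 0) jitter / sj * spec$adc_jitter_sd else jitter
    } else {
      jitter <- array(0, dims)
    }
    base <- if (spec$tumor_class == "benign") {
      ifelse(rho2 <= spec$core_fraction^2, spec$adc_core, spec$adc_rim)
    } else {
      array(spec$adc_uniform, dims)
    }
    adc <- pmin(pmax(base + jitter, 1e-6), 4e-3)
    adc[!mask] <- NA_real_
    vols <- lapply(spec$b_values, function(b) {
      a <- array(0, dims)
      a[mask] <- spec$s0_signal * exp(-b * adc[mask])
      rician(a, if (is.finite(spec$snr)) spec$s0_signal / spec$snr else 0)
    })
  })
  list(
    dwi = dwi_series(vols, spec$b_values, sp),
    mask = roi_mask(mask, sp),
    true_adc = adc_map(adc, sp)
  )
}

#' Sample Rician-distributed magnitudes
#'
#' Magnitude-MRI noise: the magnitude of a complex signal whose real and
#' imaginary channels carry independent Gaussian noise. With noise-free
#' magnitude 0 this reduces to a Rayleigh law; with `sigma = 0` the noise-free
#' magnitude is returned exactly.
#'
#' @param a Array (or vector) of noise-free magnitudes.
#' @param sigma Noise SD per channel.
#' @return Array of noisy magnitudes, same shape as `a`.
#' @export
rician <- function(a, sigma) {
  if (sigma == 0) return(a)
  n <- length(a)
  out <- sqrt((a + stats::rnorm(n, sd = sigma))^2 + stats::rnorm(n, sd = sigma)^2)
  dim(out) <- dim(a)
  out
}

# FFT-based separable Gaussian smoothing with periodic boundary; sd_vox is the
# kernel SD per axis in voxel units.
smooth_field <- function(field, sd_vox) {
  dims <- dim(field)
  ker <- lapply(1:3, function(k) {
    n <- dims[k]
    s <- sd_vox[k]
    if (s < 1e-6) {
      v <- numeric(n); v[1] <- 1; return(v)
    }
    x <- 0:(n - 1)
    x <- pmin(x, n - x)  # wrapped distance
    v <- exp(-0.5 * (x / s)^2)
    v / sum(v)
  })
  kern <- outer(outer(ker[[1]], ker[[2]]), ker[[3]])
  out <- Re(stats::fft(stats::fft(field) * stats::fft(kern), inverse = TRUE)) / prod(dims)
  dim(out) <- dims
  out
}

#' Specify a synthetic two-group cohort
#'
#' Defaults emulate a 40-subject myxoid-containing soft-tissue tumor cohort:
#' 23 benign (12 F : 11 M, age 53.0 +/- 12.7 y, volume 15.630 +/- 14.803 cm^3)
#' and 17 malignant (6 F : 11 M, age 60.8 +/- 13.4 y, volume 139.355 +/-
#' 179.174 cm^3). Ages are drawn normal truncated at 18; tumor volumes are
#' drawn log-normal moment-matched to the requested mean/SD (the SDs approach
#' or exceed the means, which is incompatible with a normal law on positive
#' support) and truncated to [0.5, 1000] cm^3; volumes convert to ellipsoid
#' semi-axes with fixed axis ratios.
#'
#' @param n_benign,n_malignant Subject counts per group.
#' @param age_mean,age_sd Length-2 numeric (benign, malignant), years.
#' @param sex_female Length-2 numeric, female fraction per group.
#' @param volume_mean,volume_sd Length-2 numeric (benign, malignant), cm^3.
#' @param benign_template,malignant_template [phantom_spec()]s providing the
#'   per-class ADC/noise parameters; semi-axes and seed are overwritten per
#'   subject.
#' @param adc_shift_sd Length-2 numeric (benign, malignant): SD in mm^2/s of
#'   the per-subject shift of the tumor's overall ADC level (truncated at
#'   +/- 2 SD), emulating the between-subject spread of mean ADC (0.5e-3 and
#'   0.4e-3 by default, matching the observed group SDs of mean ADC).
#' @param texture_scale_sdlog Log-SD of a per-subject log-normal multiplier
#'   (truncated to [0.5, 2]) applied to the jitter SD and, for benign
#'   tumors, to the core-rim half-gap: tumors differ in how pronounced their
#'   texture is, not only in level.
#' @param smooth_scale_sdlog Log-SD of a per-subject log-normal multiplier
#'   (truncated to [0.25, 4]) on the jitter correlation length: tumors differ
#'   in the spatial grain of their texture, which lets the classes overlap
#'   partially on correlation-type features as real cohorts do.
#' @param axis_ratios Ellipsoid axis ratios used to convert a drawn volume
#'   into semi-axes (default 1 : 0.8 : 0.7).
#' @param seed Integer RNG seed for covariates and per-subject phantom seeds.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_benign = 23L, n_malignant = 17L,
                        age_mean = c(53.0, 60.8), age_sd = c(12.7, 13.4),
                        sex_female = c(12 / 23, 6 / 17),
                        volume_mean = c(15.630, 139.355),
                        volume_sd = c(14.803, 179.174),
                        benign_template = phantom_spec("benign"),
                        malignant_template = phantom_spec("malignant"),
                        axis_ratios = c(1, 0.8, 0.7),
                        adc_shift_sd = c(0.5e-3, 0.4e-3),
                        texture_scale_sdlog = 0.3,
                        smooth_scale_sdlog = 0.6,
                        seed = 1L) {
  stopifnot(n_benign >= 1, n_malignant >= 1,
            all(volume_mean > 0), all(volume_sd > 0),
            length(axis_ratios) == 3, all(axis_ratios > 0),
            inherits(benign_template, "phantom_spec"),
            inherits(malignant_template, "phantom_spec"))
  structure(list(
    n_benign = as.integer(n_benign), n_malignant = as.integer(n_malignant),
    age_mean = age_mean, age_sd = age_sd, sex_female = sex_female,
    volume_mean = volume_mean, volume_sd = volume_sd,
    benign_template = benign_template, malignant_template = malignant_template,
    axis_ratios = axis_ratios, adc_shift_sd = adc_shift_sd,
    texture_scale_sdlog = texture_scale_sdlog,
    smooth_scale_sdlog = smooth_scale_sdlog, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Moment-matched log-normal volume draw
#'
#' Returns `n` log-normal draws whose distribution has the requested
#' arithmetic mean and SD: `sdlog^2 = log(1 + (sd/mean)^2)`,
#' `meanlog = log(mean) - sdlog^2 / 2`.
#'
#' @param n Number of draws.
#' @param mean,sd Target arithmetic mean and SD (same units).
#' @param lower,upper Truncation bounds applied after drawing.
#' @return Numeric vector of length `n`.
#' @export
rlnorm_matched <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  s2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - s2 / 2
  pmin(pmax(stats::rlnorm(n, mu, sqrt(s2)), lower), upper)
}

#' Convert a tumor volume to ellipsoid semi-axes
#'
#' @param volume_cm3 Tumor volume in cm^3.
#' @param axis_ratios Length-3 axis ratios (largest first).
#' @return Numeric length-3 semi-axes in mm.
#' @export
volume_to_semiaxes <- function(volume_cm3, axis_ratios = c(1, 0.8, 0.7)) {
  v_mm3 <- volume_cm3 * 1000
  a <- (3 * v_mm3 / (4 * pi * prod(axis_ratios)))^(1 / 3)
  a * axis_ratios
}

#' Generate a synthetic cohort
#'
#' Draws per-subject covariates (age, sex, tumor volume) and builds one
#' [phantom_spec()] per subject from the class templates. Image volumes are
#' not held in memory by default: each subject's `spec` column materialises on
#' demand via [make_phantom()] (deterministically, from its own stored seed).
#'
#' @param spec A [cohort_spec()].
#' @param materialise If `TRUE`, adds list-columns `dwi`, `mask` and
#'   `true_adc` with the generated volumes (memory-heavy for large cohorts).
#' @return A tibble with columns `subject_id`, `group`, `age`, `sex`,
#'   `volume_cm3`, `seed` and list-column `spec` (plus image columns when
#'   materialised).
#' @examples
#' head(make_cohort(cohort_spec(n_benign = 3, n_malignant = 2, seed = 7)))
#' @export
make_cohort <- function(spec, materialise = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- c(spec$n_benign, spec$n_malignant)
  cohort <- withr::with_seed(spec$seed, {
    rows <- lapply(1:2, function(g) {
      ages <- rnorm_trunc(n[g], spec$age_mean[g], spec$age_sd[g], lower = 18)
      sex <- ifelse(stats::runif(n[g]) < spec$sex_female[g], "F", "M")
      vols <- rlnorm_matched(n[g], spec$volume_mean[g], spec$volume_sd[g],
                             lower = 0.5, upper = 1000)
      tibble::tibble(
        group = c("benign", "malignant")[g],
        age = round(ages, 1), sex = sex, volume_cm3 = vols
      )
    })
    out <- dplyr::bind_rows(rows)
    grp_i <- as.integer(factor(out$group, levels = c("benign", "malignant")))
    sh <- stats::rnorm(nrow(out)) * spec$adc_shift_sd[grp_i]
    out$adc_shift <- pmin(pmax(sh, -2 * spec$adc_shift_sd[grp_i]),
                          2 * spec$adc_shift_sd[grp_i])
    out$texture_scale <- pmin(pmax(
      stats::rlnorm(nrow(out), 0, spec$texture_scale_sdlog), 0.5), 2)
    out$smooth_scale <- pmin(pmax(
      stats::rlnorm(nrow(out), 0, spec$smooth_scale_sdlog), 0.25), 4)
    out$seed <- sample.int(.Machine$integer.max - 1L, nrow(out))
    out
  })
  cohort$subject_id <- sprintf("S%03d", seq_len(nrow(cohort)))
  cohort$group <- factor(cohort$group, levels = c("benign", "malignant"))
  tmpl <- list(benign = spec$benign_template, malignant = spec$malignant_template)
  clamp_adc <- function(x) pmin(pmax(x, 2e-4), 3.6e-3)
  cohort$spec <- purrr::pmap(
    list(cohort$group, cohort$volume_cm3, cohort$adc_shift,
         cohort$texture_scale, cohort$smooth_scale, cohort$seed),
    function(g, v, shift, tsc, ssc, sd_i) {
      t <- tmpl[[as.character(g)]]
      t$tumor_semiaxes_mm <- volume_to_semiaxes(v, spec$axis_ratios)
      t$grid_shape <- NULL
      if (as.character(g) == "benign") {
        centre <- (t$adc_core + t$adc_rim) / 2 + shift
        halfgap <- (t$adc_rim - t$adc_core) / 2 * tsc
        t$adc_core <- clamp_adc(centre - halfgap)
        t$adc_rim <- clamp_adc(centre + halfgap)
      } else {
        t$adc_uniform <- clamp_adc(t$adc_uniform + shift)
      }
      t$adc_jitter_sd <- t$adc_jitter_sd * tsc
      t$jitter_smooth_mm <- t$jitter_smooth_mm * ssc
      t$seed <- as.integer(sd_i)
      t
    }
  )
  cohort <- cohort[, c("subject_id", "group", "age", "sex", "volume_cm3",
                       "adc_shift", "texture_scale", "smooth_scale", "seed", "spec")]
  if (materialise) {
    ph <- purrr::map(cohort$spec, make_phantom)
    cohort$dwi <- purrr::map(ph, "dwi")
    cohort$mask <- purrr::map(ph, "mask")
    cohort$true_adc <- purrr::map(ph, "true_adc")
  }
  cohort
}

rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}
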