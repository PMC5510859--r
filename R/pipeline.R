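#' Write one subject's volumes as NIfTI files
#'
#' Writes `<id>_b0.nii.gz`, `<id>_b<b>.nii.gz` for every further b-value, and
#' `<id>_mask.nii.gz`, with the voxel spacing recorded in the header.
#'
#' @param dwi A [dwi_series()].
#' @param mask A [roi_mask()].
#' @param dir Output directory (created if missing).
#' @param id Subject identifier used as the filename stem.
#' @return Invisibly, the vector of written file paths.
#' @export
write_subject_nifti <- function(dwi, mask, dir, id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(dwi$b_values)) {
    p <- file.path(dir, sprintf("%s_b%d.nii.gz", id, as.integer(dwi$b_values[i])))
    img <- RNifti::asNifti(dwi$volumes[[i]])
    RNifti::pixdim(img) <- dwi$voxel_spacing_mm
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  pm <- file.path(dir, sprintf("%s_mask.nii.gz", id))
  img <- RNifti::asNifti(array(as.integer(mask$mask), dim(mask$mask)))
  RNifti::pixdim(img) <- mask$voxel_spacing_mm
  RNifti::writeNifti(img, pm)
  invisible(c(paths, pm))
}

#' Read one subject's volumes from NIfTI files
#'
#' Expects the naming convention of [write_subject_nifti()].
#'
#' @param dir Directory holding the files.
#' @param id Subject identifier (filename stem).
#' @param b_values Diffusion weightings to read, in s/mm^2.
#' @return A list with `dwi` ([dwi_series()]) and `mask` ([roi_mask()]).
#' @export
read_subject_nifti <- function(dir, id, b_values = c(0, 400, 800)) {
  vols <- lapply(b_values, function(b) {
    p <- file.path(dir, sprintf("%s_b%d.nii.gz", id, as.integer(b)))
    if (!file.exists(p)) stop("missing DWI volume: ", p, call. = FALSE)
    img <- RNifti::readNifti(p)
    array(as.numeric(img), dim(img))
  })
  sp <- RNifti::pixdim(RNifti::readNifti(
    file.path(dir, sprintf("%s_b%d.nii.gz", id, as.integer(b_values[1])))))[1:3]
  pm <- file.path(dir, sprintf("%s_mask.nii.gz", id))
  if (!file.exists(pm)) stop("missing mask: ", pm, call. = FALSE)
  mimg <- RNifti::readNifti(pm)
  list(dwi = dwi_series(vols, b_values, sp),
       mask = roi_mask(array(as.numeric(mimg) > 0.5, dim(mimg)), sp))
}

#' Pipeline run configuration
#'
#' @param mode `"simulate"` (generate a phantom cohort) or `"ingest"` (read
#'   NIfTI volumes named as by [write_subject_nifti()] from `input_dir`,
#'   subjects listed in `covariates_csv` with columns `subject_id`, `group`,
#'   `age`, `sex`).
#' @param out_dir Output directory for tables, reports and the manifest.
#' @param cohort A [cohort_spec()] (simulate mode).
#' @param input_dir,covariates_csv Inputs for ingest mode.
#' @param levels,connectivity,log_base Texture options (see
#'   [extract_features()]).
#' @param b_values Diffusion weightings expected on ingest.
#' @param alpha Significance level for the ANCOVA-based ROC feature filter.
#' @param roc_select `"ancova"` or `"all"` (see [roc_table()]).
#' @param write_volumes Also write each simulated subject as NIfTI under
#'   `out_dir/nifti` (simulate mode).
#' @param case_reports Subject ids (or `"all"`) for which to write per-case
#'   diagnostic bundles; `NULL` for none.
#' @param seed Seed overriding the cohort spec seed (simulate mode).
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("simulate", "ingest"), out_dir,
                       cohort = cohort_spec(),
                       input_dir = NULL, covariates_csv = NULL,
                       levels = 64L, connectivity = 26L, log_base = exp(1),
                       b_values = c(0, 400, 800), alpha = 0.05,
                       roc_select = c("ancova", "all"),
                       write_volumes = FALSE, case_reports = NULL,
                       seed = NULL) {
  mode <- match.arg(mode)
  roc_select <- match.arg(roc_select)
  if (mode == "ingest") {
    if (is.null(input_dir) || !dir.exists(input_dir)) {
      stop("ingest mode needs an existing input_dir", call. = FALSE)
    }
    if (is.null(covariates_csv) || !file.exists(covariates_csv)) {
      stop("ingest mode needs an existing covariates_csv", call. = FALSE)
    }
  } else {
    stopifnot(inherits(cohort, "cohort_spec"))
    if (!is.null(seed)) cohort$seed <- as.integer(seed)
  }
  structure(list(mode = mode, out_dir = out_dir, cohort = cohort,
                 input_dir = input_dir, covariates_csv = covariates_csv,
                 levels = as.integer(levels), connectivity = as.integer(connectivity),
                 log_base = log_base, b_values = b_values, alpha = alpha,
                 roc_select = roc_select, write_volumes = write_volumes,
                 case_reports = case_reports),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' For every subject: obtain the DWI series and ROI mask (simulated phantom
#' or ingested NIfTI), fit the ADC map, compute global features on the raw
#' ADC values, quantize to 64 levels, compute GLSZM and GLCM features, and
#' assemble the cohort feature table. Then, when both groups have at least
#' two subjects, run the statistical layer: group comparison (t-test +
#' ANCOVA), ROC analysis with Youden cutoffs, and pairwise DeLong AUC
#' comparison with Bonferroni correction. A subject whose processing fails is
#' reported and skipped; it does not abort the cohort.
#'
#' Outputs under `out_dir`: `features.csv`, `group_comparison.csv`,
#' `roc.csv`, `auc_pairwise.csv`, `manifest.json`, optional per-case report
#' files and NIfTI volumes.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `features`, `group_comparison`, `roc`,
#'   `auc_pairwise` tibbles and the `manifest` list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  if (config$mode == "simulate") {
    cohort <- make_cohort(config$cohort)
    getter <- function(row) {
      ph <- make_phantom(row$spec[[1]])
      if (isTRUE(config$write_volumes)) {
        write_subject_nifti(ph$dwi, ph$mask, file.path(config$out_dir, "nifti"),
                            row$subject_id)
      }
      ph[c("dwi", "mask")]
    }
  } else {
    cov <- utils::read.csv(config$covariates_csv, stringsAsFactors = FALSE)
    need <- c("subject_id", "group", "age", "sex")
    if (!all(need %in% names(cov))) {
      stop("covariates_csv must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    cohort <- tibble::as_tibble(cov)
    cohort$group <- factor(cohort$group, levels = c("benign", "malignant"))
    getter <- function(row) {
      read_subject_nifti(config$input_dir, row$subject_id, config$b_values)
    }
  }

  input_hashes <- list()
  feats <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    feats[[i]] <- tryCatch({
      sub <- getter(row)
      adc <- fit_adc(sub$dwi)
      fv <- extract_features(adc, sub$mask, levels = config$levels,
                             connectivity = config$connectivity,
                             log_base = config$log_base)
      if (!is.null(config$case_reports) &&
          (identical(config$case_reports, "all") ||
           row$subject_id %in% config$case_reports)) {
        render_case_report(adc, sub$mask, file.path(config$out_dir, "reports"),
                           row$subject_id, levels = config$levels,
                           connectivity = config$connectivity)
      }
      if (config$mode == "ingest") {
        fs <- file.path(config$input_dir,
                        c(sprintf("%s_b%d.nii.gz", row$subject_id,
                                  as.integer(config$b_values)),
                          sprintf("%s_mask.nii.gz", row$subject_id)))
        input_hashes[[row$subject_id]] <- as.list(tools::md5sum(fs))
      } else {
        input_hashes[[row$subject_id]] <- list(phantom_seed = row$seed)
      }
      dplyr::bind_cols(row[, intersect(c("subject_id", "group", "age", "sex"),
                                       names(row))], fv)
    }, error = function(e) {
      warning("subject ", row$subject_id, " failed and was skipped: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
  }
  features <- dplyr::bind_rows(feats)
  utils::write.csv(features, file.path(config$out_dir, "features.csv"),
                   row.names = FALSE)

  cmp <- roc <- prs <- NULL
  if (nrow(features) && all(table(features$group) >= 2)) {
    cmp <- compare_groups(features)
    utils::write.csv(cmp, file.path(config$out_dir, "group_comparison.csv"),
                     row.names = FALSE)
    roc <- roc_table(features, select = config$roc_select, alpha = config$alpha)
    if (nrow(roc)) {
      utils::write.csv(tibble::as_tibble(roc), file.path(config$out_dir, "roc.csv"),
                       row.names = FALSE)
      if (nrow(roc) >= 2) {
        prs <- auc_pairwise(features, roc$feature)
        utils::write.csv(prs, file.path(config$out_dir, "auc_pairwise.csv"),
                         row.names = FALSE)
      }
    }
  } else {
    warning("fewer than 2 subjects per group: statistics skipped, features written",
            call. = FALSE)
  }

  manifest <- list(
    software = paste0("myxtex ", as.character(utils::packageVersion("myxtex"))),
    config = list(
      mode = config$mode, levels = config$levels,
      connectivity = config$connectivity, log_base = config$log_base,
      alpha = config$alpha, roc_select = config$roc_select,
      b_values = config$b_values,
      seed = if (config$mode == "simulate") config$cohort$seed else NULL,
      fit = "log-linear least squares, unweighted, negative slopes clamped to 0",
      auc_ci = "delong (binomial-exact auxiliary)"
    ),
    n_subjects = nrow(features),
    inputs = input_hashes,
    outputs = as.list(tools::md5sum(
      list.files(config$out_dir, pattern = "\\.csv$", full.names = TRUE))),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(features = features, group_comparison = cmp, roc = roc,
                 auc_pairwise = prs, manifest = manifest))
}

#' Write a per-case diagnostic bundle
#'
#' Mirrors the per-case panels of a texture run: the central ROI slice of the
#' ADC map, the same slice of the 64-level discrete map, the in-ROI ADC
#' histogram, the GLSZM and the GLCM, each as a CSV file named
#' `<id>_<panel>.csv`.
#'
#' @param adc An [adc_map()].
#' @param mask A [roi_mask()].
#' @param dir Output directory.
#' @param id Subject identifier.
#' @param levels,connectivity Texture options.
#' @param n_bins Histogram bin count.
#' @return Invisibly, the written file paths.
#' @export
render_case_report <- function(adc, mask, dir, id, levels = 64L,
                               connectivity = 26L, n_bins = 64L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  q <- quantize(adc, mask, levels)
  # slice with the most ROI voxels
  z <- which.max(apply(mask$mask, 3, sum))
  paths <- c(
    adc_slice = file.path(dir, paste0(id, "_adc_slice.csv")),
    discrete_slice = file.path(dir, paste0(id, "_discrete_slice.csv")),
    histogram = file.path(dir, paste0(id, "_histogram.csv")),
    glszm = file.path(dir, paste0(id, "_glszm.csv")),
    glcm = file.path(dir, paste0(id, "_glcm.csv"))
  )
  utils::write.csv(adc$values[, , z], paths["adc_slice"], row.names = FALSE)
  utils::write.csv(q$levels[, , z], paths["discrete_slice"], row.names = FALSE)
  x <- adc$values[mask$mask]
  x <- x[is.finite(x)]
  h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
  utils::write.csv(data.frame(adc_mid = h$mids, count = h$counts),
                   paths["histogram"], row.names = FALSE)
  utils::write.csv(glszm_matrix(compute_glszm(q, connectivity)),
                   paths["glszm"], row.names = FALSE)
  utils::write.csv(compute_glcm(q)$p, paths["glcm"], row.names = FALSE)
  invisible(paths)
}
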