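#' Kolmogorov-Smirnov normality test (Lilliefors-corrected)
#'
#' One-sample KS test against a normal law with mean and SD estimated from
#' the data. Because the parameters are estimated, the naive KS p-value is
#' anti-conservative; the Lilliefors correction is applied.
#'
#' @param values Numeric vector, n >= 5.
#' @return The p-value, or `NA` for constant input.
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 5) stop("need at least 5 observations", call. = FALSE)
  if (stats::sd(values) == 0) return(NA_real_)
  nortest::lillie.test(values)$p.value
}

#' Two-sample Student t-test p-value
#'
#' Two-sided pooled-variance (Student) t-test for a difference in group
#' means; a Welch variant is available via `var_equal = FALSE`.
#'
#' @param values Numeric vector.
#' @param groups Factor-like with exactly two levels, same length.
#' @param var_equal Pool the variances (default `TRUE`, the Student test).
#' @return The p-value, or `NA` when the pooled variance is zero.
#' @export
group_ttest <- function(values, groups, var_equal = TRUE) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("exactly two groups required", call. = FALSE)
  sp <- split(values, groups)
  if (any(lengths(sp) < 2)) stop("need at least 2 observations per group", call. = FALSE)
  if (all(vapply(sp, stats::var, 0) == 0)) return(NA_real_)  # zero pooled variance
  stats::t.test(sp[[1]], sp[[2]], var.equal = var_equal)$p.value
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square with 1
#' degree of freedom, as used for group sex-ratio comparisons.
#'
#' @param counts 2x2 numeric matrix of counts.
#' @return The p-value.
#' @export
sex_chisq <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2)) stop("counts must be a 2x2 table", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("all table marginals must be positive", call. = FALSE)
  }
  stats::chisq.test(counts, correct = FALSE)$p.value
}

#' Covariate-adjusted group p-value (ANCOVA)
#'
#' Classical ANCOVA as an ordinary least-squares fit of
#' `feature ~ group + age + sex + volume`; the reported p-value is the
#' two-sided partial t-test of the group coefficient, i.e. the group effect
#' adjusted for the covariates.
#'
#' @param feature Numeric response.
#' @param group Two-level factor-like.
#' @param age,volume Numeric covariates.
#' @param sex Factor-like covariate.
#' @return The adjusted p-value for the group term.
#' @export
ancova_group_p <- function(feature, group, age, sex, volume) {
  d <- data.frame(feature = feature, group = droplevels(as.factor(group)),
                  age = age, sex = droplevels(as.factor(sex)), volume = volume)
  if (nlevels(d$group) != 2) stop("exactly two groups required", call. = FALSE)
  if (nrow(d) <= 5) stop("need more than 5 subjects for a 5-column design", call. = FALSE)
  if (nlevels(d$sex) < 2) {
    stop("rank-deficient design; collinear column(s): sex", call. = FALSE)
  }
  fit <- stats::lm(feature ~ group + age + sex + volume, data = d)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  sm <- stats::summary.lm(fit)$coefficients
  grp_row <- grep("^group", rownames(sm))
  unname(sm[grp_row, "Pr(>|t|)"])
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Computes the empirical AUC (Mann-Whitney statistic with half credit for
#' ties), orienting the decision rule so that AUC >= 0.5. The reported
#' `direction` is the positive-call criterion: `">"` calls a case positive
#' (malignant) when its score is >= the threshold, `"<="` when it is <= the
#' threshold. The threshold is the observed score value maximizing the Youden
#' index J = sensitivity + specificity - 1, ties broken toward higher
#' specificity. Sensitivity and specificity carry Clopper-Pearson
#' (binomial-exact) 95% CIs; the AUC carries a DeLong 95% CI and a DeLong
#' z-test p-value against AUC = 0.5, plus an auxiliary binomial-exact CI
#' (Clopper-Pearson on the winning fraction of case-control pairs).
#'
#' @param scores Numeric marker values.
#' @param labels Two-level factor-like; see `positive`.
#' @param positive Label of the positive class (default `"malignant"` when
#'   present, otherwise the second factor level).
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble of class `myxtex_roc` with columns `auc`,
#'   `auc_ci_low`, `auc_ci_high`, `auc_ci_exact_low`, `auc_ci_exact_high`,
#'   `direction`, `threshold`, `sensitivity`, `specificity` (percent, with
#'   exact CI columns), `youden_j` and `p_vs_chance`. The underlying pROC
#'   object is attached as attribute `"roc"`.
#' @export
roc_analysis <- function(scores, labels, positive = NULL, conf_level = 0.95) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop("both classes must be present", call. = FALSE)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- droplevels(labels[keep])
  if (nlevels(labels) != 2) stop("both classes must be present", call. = FALSE)
  if (is.null(positive)) {
    positive <- if ("malignant" %in% levels(labels)) "malignant" else levels(labels)[2]
  }
  negative <- setdiff(levels(labels), positive)
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(negative, positive), direction = "auto", quiet = TRUE)
  if (as.numeric(r$auc) < 0.5) {  # "auto" picks by medians; enforce AUC >= 0.5
    r <- pROC::roc(response = labels, predictor = scores,
                   levels = c(negative, positive),
                   direction = if (r$direction == "<") ">" else "<", quiet = TRUE)
  }
  auc <- as.numeric(r$auc)
  # pROC direction "<" means controls < cases, i.e. positive calls are high scores
  dir <- if (r$direction == "<") ">" else "<="
  pos_sc <- scores[labels == positive]
  neg_sc <- scores[labels == negative]
  n1 <- length(pos_sc); n0 <- length(neg_sc)

  scan <- youden_scan(pos_sc, neg_sc, dir)
  sens_ci <- stats::binom.test(scan$tp, n1, conf.level = conf_level)$conf.int
  spec_ci <- stats::binom.test(scan$tn, n0, conf.level = conf_level)$conf.int
  v <- suppressWarnings(as.numeric(pROC::var(r, method = "delong")))
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, conf.level = conf_level,
                                                 method = "delong")))
  p_chance <- if (v > 0) 2 * stats::pnorm(-abs(auc - 0.5) / sqrt(v)) else 0
  wins <- round(auc * n1 * n0)
  exact <- stats::binom.test(wins, n1 * n0, conf.level = conf_level)$conf.int

  out <- tibble::tibble(
    auc = auc, auc_ci_low = ci[1], auc_ci_high = ci[3],
    auc_ci_exact_low = exact[1], auc_ci_exact_high = exact[2],
    direction = dir, threshold = scan$threshold,
    sensitivity = 100 * scan$tp / n1,
    sensitivity_ci_low = 100 * sens_ci[1], sensitivity_ci_high = 100 * sens_ci[2],
    specificity = 100 * scan$tn / n0,
    specificity_ci_low = 100 * spec_ci[1], specificity_ci_high = 100 * spec_ci[2],
    youden_j = scan$tp / n1 + scan$tn / n0 - 1,
    p_vs_chance = p_chance, auc_var = v
  )
  class(out) <- c("myxtex_roc", class(out))
  attr(out, "roc") <- r
  out
}

# Exhaustive Youden scan over the observed score values. dir ">": positive
# call when score >= t; dir "<=": positive call when score <= t.
youden_scan <- function(pos_sc, neg_sc, dir) {
  cand <- sort(unique(c(pos_sc, neg_sc)))
  if (dir == ">") {
    tp <- vapply(cand, function(t) sum(pos_sc >= t), 0L)
    tn <- vapply(cand, function(t) sum(neg_sc < t), 0L)
  } else {
    tp <- vapply(cand, function(t) sum(pos_sc <= t), 0L)
    tn <- vapply(cand, function(t) sum(neg_sc > t), 0L)
  }
  j <- tp / length(pos_sc) + tn / length(neg_sc) - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(tn[best])]  # ties toward higher specificity
  list(threshold = cand[best], tp = tp[best], tn = tn[best], j = j[best])
}

#' Paired comparison of two AUCs (DeLong)
#'
#' Tests whether two markers measured on the same subjects differ in AUC,
#' using the DeLong covariance of the paired empirical AUCs. Reports the AUC
#' difference with a Wald 95% CI, the raw p-value and the
#' Bonferroni-adjusted p-value `min(1, p * n_pairs)`.
#'
#' @param scores_a,scores_b Numeric marker values on the same subjects.
#' @param labels Two-level factor-like.
#' @param n_pairs Number of pairwise comparisons in the family (Bonferroni
#'   multiplier; default 1).
#' @param positive Positive class label (see [roc_analysis()]).
#' @return A one-row tibble with `auc_a`, `auc_b`, `auc_diff`,
#'   `diff_ci_low/high`, `p_raw`, `p_bonferroni`.
#' @export
compare_aucs <- function(scores_a, scores_b, labels, n_pairs = 1, positive = NULL) {
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels)) {
    stop("both markers must be scored on the same subjects", call. = FALSE)
  }
  if (anyNA(scores_a) || anyNA(scores_b)) {
    stop("both markers must be scored on the same subjects (no missing scores)",
         call. = FALSE)
  }
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop("both classes must be present", call. = FALSE)
  if (is.null(positive)) {
    positive <- if ("malignant" %in% levels(labels)) "malignant" else levels(labels)[2]
  }
  negative <- setdiff(levels(labels), positive)
  ra <- pROC::roc(labels, scores_a, levels = c(negative, positive),
                  direction = "auto", quiet = TRUE)
  rb <- pROC::roc(labels, scores_b, levels = c(negative, positive),
                  direction = "auto", quiet = TRUE)
  tt <- suppressWarnings(pROC::roc.test(ra, rb, method = "delong", paired = TRUE))
  auc_a <- as.numeric(ra$auc); auc_b <- as.numeric(rb$auc)
  diff <- auc_a - auc_b
  vd <- suppressWarnings(
    as.numeric(pROC::var(ra, method = "delong")) +
      as.numeric(pROC::var(rb, method = "delong")) -
      2 * as.numeric(pROC::cov(ra, rb, method = "delong")))
  half <- stats::qnorm(0.975) * sqrt(max(vd, 0))
  tibble::tibble(
    auc_a = auc_a, auc_b = auc_b, auc_diff = diff,
    diff_ci_low = diff - half, diff_ci_high = diff + half,
    p_raw = as.numeric(tt$p.value),
    p_bonferroni = min(1, as.numeric(tt$p.value) * n_pairs)
  )
}

#' Discriminatory-power label for an AUC
#'
#' Five-bin classification, lower bound inclusive: 0.9-1 excellent, 0.8-0.9
#' good, 0.7-0.8 fair, 0.6-0.7 poor, 0.5-0.6 failure.
#'
#' @param auc Numeric AUC value(s) in `[0.5, 1]`.
#' @return Character vector of labels.
#' @export
classify_auc <- function(auc) {
  if (any(!is.finite(auc)) || any(auc < 0.5) || any(auc > 1)) {
    stop("auc must lie in [0.5, 1]", call. = FALSE)
  }
  labs <- c("failure", "poor", "fair", "good", "excellent")
  labs[pmin(findInterval(auc, c(0.5, 0.6, 0.7, 0.8, 0.9)), 5L)]
}

#' Group comparison table for a cohort feature table
#'
#' For every feature column: per-group mean and SD, per-group Lilliefors KS
#' normality p, the unadjusted pooled t-test p, and the ANCOVA p adjusted for
#' age, sex and tumor volume.
#'
#' @param features A tibble with columns `group`, `age`, `sex`, `volume_cm3`
#'   and the feature columns.
#' @param feature_cols Character vector of feature columns to compare
#'   (default: the 13 texture features plus `volume_cm3` where present).
#' @return A tibble, one row per feature.
#' @export
compare_groups <- function(features, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- intersect(texture_feature_names(with_volume = TRUE),
                              names(features))
  }
  grp <- droplevels(as.factor(features$group))
  lv <- levels(grp)
  purrr::map_dfr(feature_cols, function(fc) {
    x <- features[[fc]]
    ok <- is.finite(x)
    m <- tapply(x[ok], grp[ok], mean)
    s <- tapply(x[ok], grp[ok], stats::sd)
    ks <- vapply(lv, function(l) {
      xi <- x[ok & grp == l]
      if (length(xi) >= 5) ks_normality(xi) else NA_real_
    }, 0)
    adj <- if (fc == "volume_cm3") NA_real_ else tryCatch(
      ancova_group_p(x[ok], grp[ok], features$age[ok], features$sex[ok],
                     features$volume_cm3[ok]),
      error = function(e) NA_real_
    )
    tibble::tibble(
      feature = fc,
      mean_benign = m[[lv[1]]], sd_benign = s[[lv[1]]],
      mean_malignant = m[[lv[2]]], sd_malignant = s[[lv[2]]],
      ks_p_benign = ks[[1]], ks_p_malignant = ks[[2]],
      p_unadjusted = tryCatch(group_ttest(x[ok], grp[ok]),
                              error = function(e) NA_real_),
      p_adjusted = adj
    )
  })
}

#' ROC table across features
#'
#' Runs [roc_analysis()] for each requested feature and appends the
#' discriminatory-power label.
#'
#' @param features Cohort feature tibble with a `group` column.
#' @param feature_cols Features to analyse (default: those with ANCOVA
#'   p < `alpha` when `select = "ancova"`, else all texture features).
#' @param select `"ancova"` to keep only covariate-adjusted significant
#'   features (the convention for reporting diagnostic performance), `"all"`
#'   for every feature.
#' @param alpha Significance level for the ANCOVA filter.
#' @return A tibble, one row per feature, with the [roc_analysis()] columns
#'   plus `power`.
#' @export
roc_table <- function(features, feature_cols = NULL,
                      select = c("ancova", "all"), alpha = 0.05) {
  select <- match.arg(select)
  if (is.null(feature_cols)) {
    feature_cols <- intersect(texture_feature_names(), names(features))
    if (select == "ancova") {
      cmp <- compare_groups(features, feature_cols)
      keep <- cmp$feature[!is.na(cmp$p_adjusted) & cmp$p_adjusted < alpha]
      feature_cols <- keep
    }
  }
  purrr::map_dfr(feature_cols, function(fc) {
    x <- features[[fc]]
    ok <- is.finite(x)
    res <- roc_analysis(x[ok], features$group[ok])
    res <- tibble::as_tibble(res)
    dplyr::bind_cols(tibble::tibble(feature = fc), res,
                     tibble::tibble(power = classify_auc(res$auc)))
  })
}

#' Pairwise AUC comparison table
#'
#' All pairwise DeLong comparisons among the requested features, Bonferroni
#' multiplier = number of pairs actually performed.
#'
#' @param features Cohort feature tibble with a `group` column.
#' @param feature_cols Features to compare (>= 2).
#' @return A tibble, one row per unordered feature pair, columns `feature_a`,
#'   `feature_b` plus the [compare_aucs()] columns.
#' @export
auc_pairwise <- function(features, feature_cols) {
  stopifnot(length(feature_cols) >= 2)
  prs <- utils::combn(feature_cols, 2)
  n_pairs <- ncol(prs)
  purrr::map_dfr(seq_len(n_pairs), function(k) {
    fa <- prs[1, k]; fb <- prs[2, k]
    dplyr::bind_cols(
      tibble::tibble(feature_a = fa, feature_b = fb),
      compare_aucs(features[[fa]], features[[fb]], features$group,
                   n_pairs = n_pairs)
    )
  })
}

#' @export
tidy.myxtex_roc <- function(x, ...) {
  r <- attr(x, "roc")
  tibble::tibble(
    threshold = r$thresholds,
    sensitivity = r$sensitivities,
    specificity = r$specificities
  )
}

#' @export
glance.myxtex_roc <- function(x, ...) {
  tibble::as_tibble(x)[, c("auc", "auc_ci_low", "auc_ci_high", "direction",
                           "threshold", "sensitivity", "specificity",
                           "youden_j", "p_vs_chance")]
}
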