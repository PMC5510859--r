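test_that("Lilliefors KS holds its level and detects non-normality", {
  set.seed(301)
  p_norm <- replicate(100, ks_normality(stats::rnorm(200)))
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_exp <- replicate(100, ks_normality(stats::rexp(200)))
  expect_gte(mean(p_exp < 0.05), 0.95)
  # location-scale invariance of the statistic
  x <- stats::rnorm(50)
  expect_equal(ks_normality(x), ks_normality(3 + 2 * x), tolerance = 1e-12)
  expect_true(is.na(ks_normality(rep(1, 10))))
  expect_error(ks_normality(c(1, 2, 3)), "at least 5")
})

test_that("pooled t-test matches R and an exhaustive permutation oracle", {
  # identical groups: t = 0, p = 1
  expect_equal(group_ttest(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3)), 1)
  # label swap leaves p unchanged
  set.seed(17)
  x <- stats::rnorm(20)
  g <- rep(c("a", "b"), 10)
  g2 <- ifelse(g == "a", "b", "a")
  expect_equal(group_ttest(x, g), group_ttest(x, g2))
  # strongly separated groups: exhaustive 70-split permutation oracle puts
  # the observed split at the extreme (p_perm = 2/70) and the t-test agrees
  # that the difference is significant
  xa <- c(1, 2, 3, 4); xb <- c(11, 12, 13, 14)
  vals <- c(xa, xb)
  splits <- utils::combn(8, 4)
  tobs <- abs(mean(xa) - mean(xb))
  tperm <- apply(splits, 2, function(ix) abs(mean(vals[ix]) - mean(vals[-ix])))
  p_perm <- mean(tperm >= tobs - 1e-12)
  expect_equal(p_perm, 2 / 70)
  p_t <- group_ttest(vals, rep(c("a", "b"), each = 4))
  expect_lt(p_t, 0.001)
  # on overlapping draws the Student p approximates the permutation p
  set.seed(31)
  for (k in 1:5) {
    v <- stats::rnorm(8)
    pp <- mean(apply(splits, 2, function(ix) {
      abs(mean(v[ix]) - mean(v[-ix]))
    }) >= abs(mean(v[1:4]) - mean(v[5:8])) - 1e-12)
    pt <- group_ttest(v, rep(c("a", "b"), each = 4))
    expect_lt(abs(pp - pt), 0.15)
  }
  # zero pooled variance is undefined
  expect_true(is.na(group_ttest(c(1, 1, 2, 2), c("a", "a", "b", "b"))))
})

test_that("uncorrected chi-square reproduces closed forms", {
  expect_equal(sex_chisq(matrix(c(12, 11, 6, 11), 2, 2, byrow = TRUE)),
               0.289, tolerance = 0.002)
  expect_equal(sex_chisq(matrix(c(10, 10, 5, 5), 2, 2, byrow = TRUE)), 1)
  # [[20,0],[0,20]]: all expected counts 10, chi-square = 40
  p <- sex_chisq(matrix(c(20, 0, 0, 20), 2, 2, byrow = TRUE))
  expect_equal(p, stats::pchisq(40, df = 1, lower.tail = FALSE))
  expect_error(sex_chisq(matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)), "marginal")
})

test_that("ANCOVA group p matches a normal-equations oracle and absorbs covariate effects", {
  set.seed(41)
  n <- 60
  group <- rep(c("benign", "malignant"), each = n / 2)
  age <- stats::rnorm(n, 55, 12)
  sex <- sample(c("F", "M"), n, TRUE)
  volume <- stats::rlnorm(n, 3, 0.8)
  y <- 1 + 0.5 * (group == "malignant") + 0.02 * age + 0.1 * (sex == "M") +
    0.01 * volume + stats::rnorm(n)
  p_pkg <- ancova_group_p(y, group, age, sex, volume)
  # independent oracle: solve the normal equations directly
  X <- cbind(1, group == "malignant", age, sex == "M", volume)
  bhat <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% bhat
  s2 <- sum(res^2) / (n - ncol(X))
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  p_oracle <- 2 * stats::pt(-abs(bhat[2] / se), df = n - ncol(X))
  expect_equal(p_pkg, p_oracle, tolerance = 1e-10)

  # a feature driven purely by volume, with volume confounded with group:
  # unadjusted test fires, covariate adjustment absorbs the effect
  set.seed(43)
  g3 <- rep(c("benign", "malignant"), 20)
  vol3 <- stats::rlnorm(40, 2 + 1.5 * (g3 == "malignant"), 0.5)
  y3 <- 2 * vol3 + stats::rnorm(40, 0, 0.5)
  expect_lt(group_ttest(y3, g3), 1e-4)
  p_abs <- ancova_group_p(y3, g3, stats::rnorm(40, 55, 10),
                          sample(c("F", "M"), 40, TRUE), vol3)
  expect_gt(p_abs, 0.05)

  # with covariates independent of group and feature, adjusted ~ unadjusted
  set.seed(47)
  diffs <- replicate(20, {
    n2 <- 2000
    g2 <- rep(c("benign", "malignant"), each = n2 / 2)
    y2 <- stats::rnorm(n2) + 0.1 * (g2 == "malignant")
    a2 <- stats::rnorm(n2, 50, 10); s2x <- sample(c("F", "M"), n2, TRUE)
    v2 <- stats::rlnorm(n2, 2, 0.6)
    abs(ancova_group_p(y2, g2, a2, s2x, v2) - group_ttest(y2, g2))
  })
  expect_lt(mean(diffs), 0.01)

  # rank-deficient design names the collinear column
  expect_error(ancova_group_p(stats::rnorm(20), rep(c("a", "b"), 10),
                              stats::rnorm(20), rep("F", 20),
                              stats::rlnorm(20)),
               "collinear")
})

test_that("empirical AUC equals the pair-counting oracle and orients above 0.5", {
  set.seed(53)
  for (k in 1:25) {
    n1 <- sample(3:25, 1); n0 <- sample(3:25, 1)
    sc <- c(stats::rnorm(n0), stats::rnorm(n1, sample(c(-1, 1), 1)))
    if (stats::runif(1) < 0.3) sc <- round(sc)  # force ties sometimes
    lab <- factor(rep(c("benign", "malignant"), c(n0, n1)))
    r <- roc_analysis(sc, lab)
    a_or <- oracle_auc(sc[lab == "malignant"], sc[lab == "benign"])
    expect_equal(r$auc, max(a_or, 1 - a_or), tolerance = 1e-12)
    expect_gte(r$auc, 0.5)
    expect_equal(r$youden_j, r$sensitivity / 100 + r$specificity / 100 - 1,
                 tolerance = 1e-12)
  }
})

test_that("the Youden threshold equals the exhaustive-scan arg-max", {
  set.seed(59)
  for (k in 1:20) {
    sc <- round(c(stats::rnorm(15, 0), stats::rnorm(12, 1.2)), 1)
    lab <- factor(rep(c("benign", "malignant"), c(15, 12)))
    r <- roc_analysis(sc, lab)
    o <- oracle_youden(sc[lab == "malignant"], sc[lab == "benign"], r$direction)
    expect_equal(r$threshold, o$threshold)
    expect_equal(r$youden_j, o$j, tolerance = 1e-12)
    expect_equal(r$sensitivity, 100 * o$se, tolerance = 1e-9)
    expect_equal(r$specificity, 100 * o$sp, tolerance = 1e-9)
  }
})

test_that("perfect separation gives AUC 1 with 100/100 operating point", {
  r <- roc_analysis(c(1, 2, 3, 4, 5, 6),
                    factor(rep(c("benign", "malignant"), each = 3)))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_equal(r$youden_j, 1)
  # documented tie example: benign {1,2}, malignant {2,3} -> (3 + 0.5)/4
  r2 <- roc_analysis(c(1, 2, 2, 3),
                     factor(c("benign", "benign", "malignant", "malignant")))
  expect_equal(r2$auc, 0.875)
  expect_error(roc_analysis(1:5, factor(rep("benign", 5))), "both classes")
})

test_that("label-permuted scores give chance-level raw AUC", {
  set.seed(61)
  sc <- stats::rnorm(40)
  lab <- rep(c("benign", "malignant"), c(23, 17))
  aucs <- replicate(500, {
    pl <- sample(lab)
    oracle_auc(sc[pl == "malignant"], sc[pl == "benign"])
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
})

test_that("DeLong machinery: self-comparison is null, Bonferroni is monotone", {
  set.seed(67)
  x <- stats::rnorm(40); lab <- rep(c("benign", "malignant"), c(23, 17))
  self <- compare_aucs(x, x, lab)
  expect_equal(self$auc_diff, 0)
  expect_equal(self$p_raw, 1)
  y <- stats::rnorm(40)
  cmp <- compare_aucs(x, y, lab, n_pairs = 15)
  expect_gte(cmp$p_bonferroni, cmp$p_raw)
  expect_lte(cmp$p_bonferroni, 1)
  expect_equal(cmp$p_bonferroni, min(1, cmp$p_raw * 15))
  expect_error(compare_aucs(x[1:30], y, lab), "same subjects")
})

test_that("paired AUC test is never anti-conservative under the null", {
  # at n = 40 the AUC difference is discrete (increments of 1/391) and the
  # DeLong z-test is conservative, so its null p-values are stochastically
  # larger than uniform; what matters for inference is that rejection never
  # exceeds the nominal level
  set.seed(71)
  lab <- rep(c("benign", "malignant"), c(23, 17))
  ps <- replicate(500, {
    compare_aucs(stats::rnorm(40), stats::rnorm(40), lab)$p_raw
  })
  expect_lte(mean(ps < 0.05), 0.065)
  expect_lte(mean(ps < 0.10), 0.12)
  expect_gte(stats::median(ps), 0.4)
})

test_that("AUC bins follow the discriminatory-power convention", {
  expect_equal(classify_auc(0.923), "excellent")
  expect_equal(classify_auc(0.85), "good")
  expect_equal(classify_auc(0.5), "failure")
  expect_equal(classify_auc(c(0.9, 0.8, 0.7, 0.6, 1.0)),
               c("excellent", "good", "fair", "poor", "excellent"))
  expect_error(classify_auc(0.4), "0.5")
  expect_error(classify_auc(1.2), "0.5")
})

test_that("cohort-level tables are assembled per feature", {
  set.seed(73)
  n <- 30
  feats <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:n),
    group = factor(rep(c("benign", "malignant"), c(16, 14))),
    age = stats::rnorm(n, 55, 10),
    sex = sample(c("F", "M"), n, TRUE),
    volume_cm3 = stats::rlnorm(n, 2, 0.7),
    contrast = stats::rnorm(n, 80, 20) - 30 * (rep(c(0, 1), c(16, 14))),
    energy = stats::runif(n, 0.001, 0.01)
  )
  cmp <- compare_groups(feats, c("contrast", "energy"))
  expect_equal(cmp$feature, c("contrast", "energy"))
  expect_true(all(cmp$p_unadjusted >= 0 & cmp$p_unadjusted <= 1))
  expect_true(all(cmp$p_adjusted >= 0 & cmp$p_adjusted <= 1))
  rt <- roc_table(feats, c("contrast", "energy"), select = "all")
  expect_equal(nrow(rt), 2)
  expect_true(all(rt$auc >= 0.5))
  pw <- auc_pairwise(feats, c("contrast", "energy"))
  expect_equal(nrow(pw), 1)
  # tidy/glance expose the ROC curve and its summary
  r <- roc_analysis(feats$contrast, feats$group)
  td <- tidy(r)
  expect_true(all(c("threshold", "sensitivity", "specificity") %in% names(td)))
  expect_equal(glance(r)$auc, r$auc)
})
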