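.stat_result <- function(feature = NA_character_, test, statistic, p_value,
                         direction = NA_character_, ...) {
  tibble(feature = feature, test = test, statistic = statistic,
         p_value = p_value, effect_direction = direction, ...)
}

#' Two-sample t-test, optionally covariate-adjusted
#'
#' Without covariates: Student's equal-variance t-test (the default;
#' `welch = TRUE` gives the unequal-variance form). With covariates the
#' comparison is the group-coefficient t-test in the linear model
#' `value ~ group + covariates`.
#'
#' @param x,y Numeric values for groups A and B.
#' @param covariates Optional data frame with `length(x) + length(y)` rows
#'   (x rows first) of nuisance variables.
#' @param welch Use the Welch statistic (no covariates only).
#' @param feature Optional feature label carried into the result.
#' @return One-row tibble (StatResult): test, statistic, p_value, effect
#'   direction, group means/SDs/sizes.
#' @export
two_sample_t <- function(x, y, covariates = NULL, welch = FALSE,
                         feature = NA_character_) {
  if (length(x) < 2 || length(y) < 2) abort("each group needs >= 2 values")
  if (var(x) == 0 && var(y) == 0) abort("zero variance in both groups")
  direction <- if (mean(x) >= mean(y)) "A>B" else "A<B"
  base_cols <- list(mean_a = mean(x), mean_b = mean(y),
                    sd_a = sd(x), sd_b = sd(y),
                    n_a = length(x), n_b = length(y))
  if (is.null(covariates)) {
    tt <- t.test(x, y, var.equal = !welch)
    return(do.call(.stat_result, c(list(
      feature = feature,
      test = if (welch) "welch_t" else "student_t",
      statistic = unname(tt$statistic), p_value = tt$p.value,
      direction = direction), base_cols)))
  }
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(x) + length(y)) {
    abort("covariates must have one row per observation (x first)")
  }
  df <- cbind(data.frame(.value = c(x, y),
                         .group = rep(c("A", "B"), c(length(x), length(y)))),
              covariates)
  X <- stats::model.matrix(~ ., data = df[, -1, drop = FALSE])
  if (qr(X)$rank < ncol(X)) abort("rank-deficient design (collinear covariates)")
  fit <- lm(.value ~ ., data = df)
  sm <- summary(fit)$coefficients
  row <- grep("^\\.groupB$", rownames(sm))
  do.call(.stat_result, c(list(
    feature = feature, test = "lm_group_t",
    statistic = -sm[row, "t value"],  # orient as A vs B
    p_value = sm[row, "Pr(>|t|)"], direction = direction), base_cols))
}

#' Mann-Whitney U test
#'
#' Exact p-value (via the exact null distribution of the rank sum) when the
#' pooled sample size is at most 12 and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#' Medians and quartiles per group are reported alongside.
#'
#' @param x,y Group values.
#' @param feature Optional feature label.
#' @return One-row StatResult tibble with `statistic` = U for group A.
#' @export
mann_whitney_u <- function(x, y, feature = NA_character_) {
  if (length(x) < 1 || length(y) < 1) abort("both groups must be non-empty")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  q_x <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  q_y <- quantile(y, c(0.25, 0.5, 0.75), names = FALSE)
  .stat_result(
    feature = feature,
    test = if (exact) "mann_whitney_exact" else "mann_whitney_normal",
    statistic = unname(wt$statistic), p_value = wt$p.value,
    direction = if (q_x[2] >= q_y[2]) "A>B" else "A<B",
    median_a = q_x[2], q25_a = q_x[1], q75_a = q_x[3],
    median_b = q_y[2], q25_b = q_y[1], q75_b = q_y[3],
    n_a = length(x), n_b = length(y)
  )
}

#' Paired t-test with percent change
#'
#' One-sample t-test on post minus pre differences. Percent change per
#' subject is `(post - pre) / pre * 100`, masked (`NA`) where the
#' pre value is zero. Zero-variance nonzero-mean differences are reported
#' with a p-value at the machine floor rather than an error.
#'
#' @param pre,post Equal-length paired values.
#' @param feature Optional feature label.
#' @return One-row StatResult tibble with mean percent change and the
#'   per-subject values as a list-column.
#' @export
paired_t <- function(pre, post, feature = NA_character_) {
  if (length(pre) != length(post)) abort("pre and post must be equal length")
  if (length(pre) < 2) abort("need >= 2 pairs")
  d <- post - pre
  pct <- ifelse(pre == 0, NA_real_, (post - pre) / pre * 100)
  n_masked <- sum(pre == 0)
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      stat <- 0; p <- 1
    } else {
      stat <- sign(mean(d)) * Inf
      p <- .Machine$double.xmin
    }
  } else {
    tt <- t.test(d)
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  .stat_result(
    feature = feature, test = "paired_t", statistic = stat, p_value = p,
    direction = if (mean(d) >= 0) "post>pre" else "post<pre",
    mean_percent_change = mean(pct, na.rm = TRUE),
    n_pairs = length(pre), n_percent_masked = n_masked,
    percent_change = list(pct)
  )
}

#' Correlation between a dynamic feature and a clinical score
#'
#' Pearson or Spearman correlation with a two-sided p-value. With
#' covariates, a partial correlation: both variables are residualised on the
#' covariates (OLS) and the correlation of residuals is tested on
#' `n - 2 - q` degrees of freedom.
#'
#' @param feature_values,score Numeric vectors of equal length (>= 3).
#' @param covariates Optional data frame of nuisance variables.
#' @param method `"pearson"` or `"spearman"`.
#' @param feature Optional feature label.
#' @return One-row StatResult tibble with `statistic` = r.
#' @export
correlate <- function(feature_values, score, covariates = NULL,
                      method = c("pearson", "spearman"),
                      feature = NA_character_) {
  method <- match.arg(method)
  n <- length(feature_values)
  if (n < 3 || length(score) != n) abort("need >= 3 paired observations")
  if (sd(feature_values) == 0 || sd(score) == 0) abort("constant input")
  if (is.null(covariates)) {
    ct <- suppressWarnings(cor.test(feature_values, score, method = method))
    return(.stat_result(
      feature = feature, test = paste0(method, "_correlation"),
      statistic = unname(ct$estimate), p_value = ct$p.value,
      direction = if (ct$estimate >= 0) "positive" else "negative",
      n = n))
  }
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) abort("covariates must match observations")
  X <- stats::model.matrix(~ ., data = covariates)
  if (qr(X)$rank < ncol(X)) abort("rank-deficient covariates")
  q <- ncol(X) - 1
  if (method == "spearman") {
    feature_values <- rank(feature_values)
    score <- rank(score)
  }
  rx <- stats::resid(stats::lm.fit(X, feature_values))
  ry <- stats::resid(stats::lm.fit(X, score))
  r <- cor(rx, ry)
  dfree <- n - 2 - q
  if (dfree < 1) abort("not enough observations for partial correlation")
  tstat <- r * sqrt(dfree / (1 - r^2))
  p <- 2 * pt(-abs(tstat), dfree)
  .stat_result(
    feature = feature, test = paste0("partial_", method, "_correlation"),
    statistic = r, p_value = p,
    direction = if (r >= 0) "positive" else "negative", n = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return Vector of step-up adjusted q-values.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Kolmogorov-Smirnov normality diagnostic
#'
#' Reported as a diagnostic only; the choice between t and Mann-Whitney
#' tests is configuration-driven, never silently automatic.
#'
#' @param x Numeric vector.
#' @return One-row tibble with the KS statistic and p-value against a
#'   normal with the sample mean and SD.
#' @export
ks_normality <- function(x) {
  if (sd(x) == 0) abort("constant input")
  kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  tibble(test = "ks_normality", statistic = unname(kt$statistic),
         p_value = kt$p.value, n = length(x))
}

#' Batch group comparison over a tidy feature table
#'
#' Applies [two_sample_t()] or [mann_whitney_u()] per feature and adjusts
#' p-values with [bh_fdr()] within the supplied family.
#'
#' @param data Tidy tibble with one row per subject x feature.
#' @param value,feature_col,group_col Column names (strings) of the value,
#'   the feature id and the two-level group.
#' @param covariate_cols Optional covariate column names (t-test path only).
#' @param test `"t"` or `"mann_whitney"`.
#' @param family Family label stored in the result.
#' @return StatResult tibble, one row per feature, with `q_value`.
#' @export
compare_groups <- function(data, value, feature_col, group_col,
                           covariate_cols = NULL,
                           test = c("t", "mann_whitney"),
                           family = NA_character_) {
  test <- match.arg(test)
  groups <- sort(unique(data[[group_col]]))
  if (length(groups) != 2) abort("group column must have exactly 2 levels")
  feats <- unique(data[[feature_col]])
  res <- lapply(feats, function(f) {
    d <- data[data[[feature_col]] == f, ]
    ia <- d[[group_col]] == groups[1]
    x <- d[[value]][ia]; y <- d[[value]][!ia]
    if (test == "t") {
      covs <- if (!is.null(covariate_cols)) {
        rbind(d[ia, covariate_cols, drop = FALSE],
              d[!ia, covariate_cols, drop = FALSE])
      } else NULL
      out <- tryCatch(two_sample_t(x, y, covariates = covs, feature = as.character(f)),
                      error = function(e) NULL)
    } else {
      out <- tryCatch(mann_whitney_u(x, y, feature = as.character(f)),
                      error = function(e) NULL)
    }
    out
  })
  res <- bind_rows(res[!vapply(res, is.null, logical(1))])
  if (nrow(res) == 0) return(res)
  res$q_value <- bh_fdr(res$p_value)
  res$family <- family
  res$group_a <- as.character(groups[1])
  res$group_b <- as.character(groups[2])
  res
}
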