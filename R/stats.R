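# Cohort-level association analysis: per-feature Pearson correlations
# against the GHQ-12 total, ordinary least squares with the full gait
# feature set, and Welch group comparisons.

# The 16 gait features, in report order: for each parameter, the pooled
# mean, its Symmetry Index, the pooled intra-subject SD, and the SD's
# Symmetry Index.
feature_names <- function() {
  unlist(lapply(GAIT_PARAMETERS, function(p)
    paste0(p, c("_mean", "_si_mean", "_sd", "_si_sd"))))
}

#' Pearson correlation with a classical two-sided p-value
#'
#' Product-moment correlation; the p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3), each with nonzero
#'   variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_gaitsym("need equal-length vectors with n >= 3",
                 "gaitsym_degenerate_input_error")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0)
    stop_gaitsym("zero variance or too few complete pairs",
                 "gaitsym_degenerate_input_error")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlation table of gait features against GHQ-12 totals
#'
#' One row per gait feature, in the standard report order (per parameter:
#' mean, SI of the mean, SD, SI of the SD), each correlated with
#' `ghq_total`. Significance is flagged at p < 0.05 (no multiple-testing
#' correction by default, matching common practice in exploratory gait
#' studies; set `adjust = "BH"` for Benjamini-Hochberg).
#'
#' @param cohort data.frame with `ghq_total` and the 16 gait feature
#'   columns (see [extract_features()]).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame `feature, r, p, n, significant` (and `p_adj` when
#'   adjusted).
#' @export
correlation_table <- function(cohort, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  feats <- feature_names()
  missing <- setdiff(c("ghq_total", feats), names(cohort))
  if (length(missing))
    stop_gaitsym(paste0("cohort table missing columns: ",
                        paste(missing, collapse = ", ")),
                 "gaitsym_format_error")
  rows <- lapply(feats, function(f) {
    res <- tryCatch(pearson_correlation(cohort[[f]], cohort$ghq_total),
                    gaitsym_degenerate_input_error = function(e)
                      stop_gaitsym(paste0(f, ": ", conditionMessage(e)),
                                   "gaitsym_degenerate_input_error"))
    data.frame(feature = f, r = res$r, p = res$p, n = res$n)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- (if (adjust == "BH") out$p_adj else out$p) < 0.05
  out
}

#' Ordinary least squares of GHQ-12 totals on gait features
#'
#' Multiple regression with intercept; reports the overall multiple
#' correlation, R-squared, the overall F test with its degrees of freedom,
#' and unstandardized coefficients with t statistics and two-sided
#' p-values.
#'
#' @param cohort data.frame containing `response` and all `predictors`.
#' @param predictors character vector of predictor column names; default
#'   is the 16 gait features plus `age` when present (17 predictors).
#' @param response response column, default `"ghq_total"`.
#' @return list with `r`, `r_squared`, `F`, `df1`, `df2`, `p`,
#'   `coefficients` (data.frame), `n`, `predictors`.
#' @export
fit_ols <- function(cohort, predictors = NULL, response = "ghq_total") {
  if (is.null(predictors)) {
    predictors <- feature_names()
    if ("age" %in% names(cohort)) predictors <- c(predictors, "age")
  }
  missing <- setdiff(c(response, predictors), names(cohort))
  if (length(missing))
    stop_gaitsym(paste0("missing columns: ", paste(missing, collapse = ", ")),
                 "gaitsym_format_error")
  dat <- cohort[, c(response, predictors)]
  dat <- dat[complete.cases(dat), ]
  n <- nrow(dat)
  p <- length(predictors)
  if (n <= p + 1)
    stop_gaitsym(sprintf("need n > p + 1 (n = %d, p = %d)", n, p),
                 "gaitsym_degenerate_input_error")
  mm <- as.matrix(cbind(1, dat[, predictors]))
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop_gaitsym(paste0("design matrix is rank deficient; collinear column(s): ",
                        paste(aliased, collapse = ", ")),
                 "gaitsym_collinearity_error")
  }
  fml <- stats::reformulate(sprintf("`%s`", predictors),
                            response = sprintf("`%s`", response))
  fit <- lm(fml, data = dat)
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "t", "p")
  co <- cbind(term = rownames(co), co)
  rownames(co) <- NULL
  co$term <- gsub("`", "", co$term)
  fstat <- sm$fstatistic
  list(r = sqrt(sm$r.squared), r_squared = sm$r.squared,
       F = unname(fstat[1]), df1 = unname(fstat[2]), df2 = unname(fstat[3]),
       p = pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
       coefficients = co, n = n, predictors = predictors)
}

#' Welch's unequal-variance t test
#'
#' Two-sided comparison of two group means with Satterthwaite degrees of
#' freedom; used e.g. for male/female comparisons of gait variability.
#'
#' @param group_a,group_b numeric vectors, each with n >= 2.
#' @return list with `t`, `p`, `df`, `mean_diff` (a minus b).
#' @export
welch_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_gaitsym("each group needs n >= 2", "gaitsym_degenerate_input_error")
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       mean_diff = mean(group_a) - mean(group_b))
}
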