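test_that("pearson correlation matches hand computation and handles extremes", {
  x <- c(1, 2, 3, 4, 5)
  res <- pearson_correlation(x, c(2, 1, 4, 3, 5))
  expect_equal(res$r, 0.8, tolerance = 1e-12)
  expect_equal(res$n, 5)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -2 * x + 5)$r, -1)
  expect_error(pearson_correlation(x, rep(1, 5)),
               class = "gaitsym_degenerate_input_error")
  expect_error(pearson_correlation(1:2, 1:2),
               class = "gaitsym_degenerate_input_error")
})

test_that("correlation is affine-invariant with a sign flip under negation", {
  set.seed(3)
  x <- rnorm(40); y <- rnorm(40) + 0.5 * x
  r0 <- pearson_correlation(x, y)$r
  expect_equal(pearson_correlation(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_correlation(-2 * x + 1, y)$r, -r0, tolerance = 1e-12)
})

test_that("correlation_table rows agree with pearson_correlation per feature", {
  set.seed(5)
  n <- 30
  tab <- as.data.frame(setNames(
    lapply(gaitsym:::feature_names(), function(f) rnorm(n)),
    gaitsym:::feature_names()))
  tab$ghq_total <- rpois(n, 2)
  ct <- correlation_table(tab)
  expect_equal(nrow(ct), 16)
  for (k in c(1, 7, 16)) {
    ref <- pearson_correlation(tab[[ct$feature[k]]], tab$ghq_total)
    expect_equal(ct$r[k], ref$r)
    expect_equal(ct$p[k], ref$p)
  }
  expect_equal(ct$significant, ct$p < 0.05)
})

test_that("OLS reports exact fits, df bookkeeping and the F = t^2 identity", {
  set.seed(8)
  n <- 40
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d$ghq_total <- 2 + 1.5 * d$a - 0.5 * d$b + 0.25 * d$c
  # lm warns about the (intentionally) perfect fit
  fit <- suppressWarnings(fit_ols(d, predictors = c("a", "b", "c")))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$df1, 3)
  expect_equal(fit$df2, n - 4)
  expect_equal(fit$coefficients$estimate,
               c(2, 1.5, -0.5, 0.25), tolerance = 1e-9)
  # single predictor: overall F equals the squared correlation t statistic
  d$y2 <- d$a + rnorm(n)
  f1 <- fit_ols(d, predictors = "a", response = "y2")
  r <- pearson_correlation(d$a, d$y2)
  t_stat <- r$r * sqrt((n - 2) / (1 - r$r^2))
  expect_equal(f1$F, t_stat^2, tolerance = 1e-9)
})

test_that("rank-deficient designs raise a collinearity error naming columns", {
  set.seed(9)
  d <- data.frame(a = rnorm(20))
  d$b <- 2 * d$a
  d$ghq_total <- rnorm(20)
  err <- expect_error(fit_ols(d, predictors = c("a", "b")),
                      class = "gaitsym_collinearity_error")
  expect_match(conditionMessage(err), "b")
  expect_error(fit_ols(d[1:3, ], predictors = c("a", "b")),
               class = "gaitsym_degenerate_input_error")
})

test_that("OLS residuals are orthogonal to every predictor", {
  set.seed(10)
  n <- 60
  d <- as.data.frame(matrix(rnorm(n * 5), n))
  names(d) <- paste0("p", 1:5)
  d$ghq_total <- rowSums(d) + rnorm(n)
  fit <- fit_ols(d, predictors = paste0("p", 1:5))
  co <- fit$coefficients$estimate
  resid <- d$ghq_total - (co[1] + as.matrix(d[, paste0("p", 1:5)]) %*% co[-1])
  for (p in paste0("p", 1:5))
    expect_lt(abs(sum(resid * scale(d[[p]]))), 1e-8)
})

test_that("Welch test matches a permutation oracle and handles separation", {
  ident <- welch_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  shifted <- welch_ttest(c(1, 2, 3), c(11, 12, 13) + c(1e-3, -1e-3, 0))
  expect_lt(shifted$p, 0.01)
  expect_error(welch_ttest(1, c(1, 2)), class = "gaitsym_degenerate_input_error")
  # permutation comparison on a moderate example
  set.seed(12)
  a <- rnorm(12, 0.3); b <- rnorm(15, 0)
  obs <- welch_ttest(a, b)
  pool <- c(a, b)
  perm <- replicate(20000, {
    idx <- sample(length(pool), length(a))
    mean(pool[idx]) - mean(pool[-idx])
  })
  p_perm <- mean(abs(perm) >= abs(mean(a) - mean(b)))
  expect_lt(abs(obs$p - p_perm), 0.02)
})

test_that("the full feature set outpredicts any single feature on a coupled cohort", {
  co <- simulate_cohort(small_cohort_spec(n_subjects = 40, n_strides = 10),
                        seed = 77)
  f <- extract_features(co, pipeline_config(min_steps = 10))
  tab <- merge(f, score_ghq12(co$ghq), by = "subject_id")
  full <- fit_ols(tab, predictors = gaitsym:::feature_names())
  singles <- vapply(gaitsym:::feature_names(), function(p)
    fit_ols(tab, predictors = p)$r_squared, numeric(1))
  expect_gt(full$r_squared, max(singles))
})
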