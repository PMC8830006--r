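make_groups_df <- function(values, groups) {
  tibble::tibble(value = values, group = groups)
}

test_that("group comparison routes through the normality gate", {
  # exactly normal group shapes (normal quantiles) with a large shift
  # -> ANOVA path, post-hoc flags the pair
  shape <- qnorm(ppoints(50))
  df <- make_groups_df(c(shape, shape + 3), rep(c("a", "b"), each = 50))
  gc <- compare_groups(df, "value")
  expect_equal(gc$test_used, "anova_tukey")
  expect_lt(gc$omnibus_p, 0.001)
  expect_false(is.null(gc$posthoc))
  expect_lt(gc$posthoc$p[1], 0.001)

  # heavily skewed group shapes (exponential quantiles) -> Kruskal-Wallis path
  skew <- qexp(ppoints(60))
  df2 <- make_groups_df(c(skew, skew + 2, skew),
                        rep(c("a", "b", "c"), each = 60))
  gc2 <- compare_groups(df2, "value")
  expect_equal(gc2$test_used, "kruskal_wallis_mc")
  expect_lt(gc2$omnibus_p, 0.001)
  expect_true(any(grepl("b", gc2$posthoc$group_pair)))
})

test_that("group comparison keeps type-I error near nominal under the null", {
  set.seed(202)
  rejections <- 0L
  n_rep <- 200
  for (k in seq_len(n_rep)) {
    df <- make_groups_df(rnorm(150), rep(c("a", "b", "c"), each = 50))
    gc <- compare_groups(df, "value")
    if (gc$omnibus_p < 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / n_rep, 0.01)
  expect_lt(rejections / n_rep, 0.10)
})

test_that("undefined values are excluded pairwise and counted", {
  df <- make_groups_df(c(rnorm(30), NA, NA, rnorm(30)),
                       rep(c("a", "b"), each = 31))
  gc <- compare_groups(df, "value")
  expect_equal(gc$summary$n, c(30L, 30L))
  expect_equal(gc$summary$n_undefined, c(1L, 1L))
})

test_that("group comparison errors name the offending group", {
  df <- make_groups_df(c(rnorm(10), 1, 2), c(rep("big", 10), "tiny", "tiny"))
  expect_error(compare_groups(df, "value"), "tiny")
})

test_that("tertile boundaries interpolate percentiles and ties go down", {
  ts <- tertile_split(1:9)
  expect_equal(ts$boundaries, c(11/3, 19/3), tolerance = 1e-12)
  expect_equal(ts$assignment, c(1, 1, 1, 2, 2, 2, 3, 3, 3))
  expect_error(tertile_split(rep(5, 10)), "distinct")
  # a value exactly on a boundary joins the lower tertile
  ts2 <- tertile_split(c(1, 2, 2, 3, 4))
  expect_equal(ts2$assignment[ts2$boundaries[1] == c(1, 2, 2, 3, 4)],
               rep(1L, sum(ts2$boundaries[1] == c(1, 2, 2, 3, 4))))
  # near-balanced counts on continuous data
  set.seed(5)
  ts3 <- tertile_split(rnorm(300))
  expect_lte(diff(range(ts3$counts)), 1)
  expect_true(ts3$boundaries[1] < ts3$boundaries[2])
})

test_that("logistic OR on a binary predictor equals the cross-product ratio", {
  df <- tibble::tibble(
    aneurysm = c(rep(1, 10), rep(0, 10)),
    exposed = c(rep(1, 8), rep(0, 2), rep(1, 4), rep(0, 6))
  )
  fit <- univariate_logistic(df, "exposed")
  expect_equal(fit$or_table$or, (8 * 6) / (2 * 4), tolerance = 1e-6)
})

test_that("null predictors give CIs containing 1", {
  set.seed(99)
  df <- tibble::tibble(aneurysm = rep(c(0, 1), each = 250), x = rnorm(500))
  fit <- univariate_logistic(df, "x")
  expect_lt(fit$or_table$ci_low, 1)
  expect_gt(fit$or_table$ci_high, 1)
})

test_that("tertile coding yields reference plus two OR rows", {
  set.seed(17)
  x <- rnorm(300, 100, 20)
  p <- plogis((x - 100) / 10)
  df <- tibble::tibble(aneurysm = rbinom(300, 1, p), x = x)
  fit <- univariate_logistic(df, "x", coding = "tertile")
  expect_equal(nrow(fit$or_table), 2)
  expect_match(fit$or_table$term[2], "T3")
  expect_gt(fit$or_table$or[2], fit$or_table$or[1])
})

test_that("perfect separation is flagged, not fatal", {
  df <- tibble::tibble(aneurysm = rep(c(0, 1), each = 15),
                       x = c(rnorm(15, 0), rnorm(15, 50)))
  fit <- univariate_logistic(df, "x")
  expect_true(fit$or_table$separation[1])
})

test_that("degenerate predictors are rejected", {
  df <- tibble::tibble(aneurysm = rep(c(0, 1), each = 15), x = rep(1, 30))
  expect_error(univariate_logistic(df, "x"), "no variation|distinct")
})

test_that("stepwise multivariate model recovers two independent effects", {
  set.seed(314)
  n <- 600
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n) # x3 is pure noise
  p <- plogis(-0.2 + 0.9 * x1 + 0.9 * x2)
  df <- tibble::tibble(aneurysm = rbinom(n, 1, p), x1 = x1, x2 = x2, x3 = x3)
  m <- multivariate_logistic(
    df, c(x1 = "continuous", x2 = "continuous", x3 = "continuous"))
  expect_setequal(m$retained, c("x1", "x2"))
  expect_true(all(m$or_table$ci_low > 1))
  expect_true("x3" %in% m$dropped$predictor)
})

test_that("correlated duplicate predictors are pruned to one", {
  set.seed(42)
  n <- 400
  x1 <- rnorm(n)
  p <- plogis(x1)
  df <- tibble::tibble(aneurysm = rbinom(n, 1, p), x1 = x1, x1_copy = x1)
  m <- multivariate_logistic(df, c(x1 = "continuous", x1_copy = "continuous"))
  expect_length(intersect(c("x1", "x1_copy"), m$retained), 1)
  expect_true(any(grepl("exceeds", m$dropped$reason)))
})

test_that("a candidate far above the entry gate never enters", {
  set.seed(8)
  n <- 400
  x1 <- rnorm(n)
  p <- plogis(x1)
  df <- tibble::tibble(aneurysm = rbinom(n, 1, p), x1 = x1, junk = rnorm(n))
  m <- multivariate_logistic(df, c(x1 = "continuous", junk = "continuous"))
  expect_false("junk" %in% m$retained)
})

test_that("ROC AUC matches exhaustive pair counting and handles ties", {
  df <- tibble::tibble(aneurysm = c(1, 1, 1, 0, 0), x = c(2, 3, 4, 1, 2))
  r <- roc_analysis(df, "x")
  expect_equal(r$auc, (5 + 0.5) / 6, tolerance = 1e-12)
  expect_equal(r$auc, oracle_auc_paircount(c(2, 3, 4), c(1, 2)),
               tolerance = 1e-12)

  set.seed(77)
  for (k in 1:50) {
    nc <- sample(3:12, 1); nn <- sample(3:12, 1)
    cases <- sample(1:6, nc, replace = TRUE)
    controls <- sample(1:6, nn, replace = TRUE)
    df2 <- tibble::tibble(aneurysm = rep(c(1, 0), c(nc, nn)),
                          x = c(cases, controls))
    r2 <- roc_analysis(df2, "x")
    expect_equal(r2$auc, oracle_auc_paircount(cases, controls),
                 tolerance = 1e-12)
  }
})

test_that("perfect separation gives AUC 1 at the separating midpoint", {
  df <- tibble::tibble(aneurysm = rep(c(1, 0), each = 5),
                       x = c(6:10, 1:5))
  r <- roc_analysis(df, "x")
  expect_equal(r$auc, 1)
  expect_equal(r$youden, 1)
  expect_equal(r$cutoff, 5.5)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
})

test_that("ROC of a useless predictor sits near the diagonal", {
  set.seed(123)
  df <- tibble::tibble(aneurysm = sample(rep(c(0, 1), 500)), x = rnorm(1000))
  r <- roc_analysis(df, "x")
  expect_lt(abs(r$auc - 0.5), 0.05)
  expect_error(roc_analysis(df[df$aneurysm == 1, ], "x"), "both outcome")
})

test_that("ROC agrees with the reference implementation in pROC", {
  skip_if_not_installed("pROC")
  set.seed(55)
  df <- tibble::tibble(aneurysm = rep(c(1, 0), c(40, 60)),
                       x = c(rnorm(40, 1), rnorm(60)))
  r <- roc_analysis(df, "x")
  pr <- pROC::roc(df$aneurysm, df$x, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  best <- pROC::coords(pr, "best", best.method = "youden", transpose = FALSE)
  expect_equal(r$cutoff, min(best$threshold), tolerance = 1e-9)
})
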