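dct_ann <- function(x_by_gene, status) {
  n <- length(status)
  ids <- sprintf("S%03d", seq_len(n))
  dct <- purrr::map_dfr(names(x_by_gene), function(g) {
    tibble::tibble(sample_id = ids, gene = g, delta_ct = x_by_gene[[g]])
  })
  list(dct = dct,
       ann = tibble::tibble(sample_id = ids, ln_status = status))
}

test_that("mirror-image groups give an odds ratio of exactly 1", {
  d <- dct_ann(list(GA = c(1, 2, 1, 2)),
               c("POSITIVE", "POSITIVE", "NEGATIVE", "NEGATIVE"))
  row <- univariate_or(d$dct, d$ann)
  expect_equal(row$odds_ratio, 1, tolerance = 1e-8)
  expect_true(row$ci_low <= row$odds_ratio && row$odds_ratio <= row$ci_high)
})

test_that("odds ratios are shift-invariant and scale as beta/k", {
  set.seed(31)
  x <- rnorm(80)
  y <- rbinom(80, 1, plogis(0.4 * x))
  status <- ifelse(y == 1, "POSITIVE", "NEGATIVE")
  base <- univariate_or(dct_ann(list(GA = x), status)$dct,
                        dct_ann(list(GA = x), status)$ann)
  shifted <- univariate_or(dct_ann(list(GA = x + 7), status)$dct,
                           dct_ann(list(GA = x), status)$ann)
  expect_equal(shifted$odds_ratio, base$odds_ratio, tolerance = 1e-8)
  scaled <- univariate_or(dct_ann(list(GA = 3 * x), status)$dct,
                          dct_ann(list(GA = x), status)$ann)
  expect_equal(log(scaled$odds_ratio), log(base$odds_ratio) / 3,
               tolerance = 1e-8)
})

test_that("separation and constant predictors are flagged, not fatal", {
  d <- dct_ann(list(GA = c(1, 2, 3, 10, 11, 12)),
               c(rep("NEGATIVE", 3), rep("POSITIVE", 3)))
  row <- univariate_or(d$dct, d$ann)
  expect_match(row$note, "separation")
  expect_equal(row$ci_low, 0)
  expect_equal(row$ci_high, Inf)

  d2 <- dct_ann(list(GA = rep(4, 6)),
                c(rep("NEGATIVE", 3), rep("POSITIVE", 3)))
  row2 <- univariate_or(d2$dct, d2$ann)
  expect_true(is.na(row2$odds_ratio))
  expect_match(row2$note, "constant")

  d3 <- dct_ann(list(GA = c(1, 2, 3)), c("NEGATIVE", "NEGATIVE", "POSITIVE"))
  expect_match(univariate_or(d3$dct, d3$ann)$note, "fewer than 2")
})

test_that("the OR table covers each requested gene once", {
  set.seed(8)
  d <- dct_ann(list(GA = rnorm(40), GB = rnorm(40)),
               rep(c("POSITIVE", "NEGATIVE"), 20))
  tab <- univariate_or(d$dct, d$ann)
  expect_equal(sort(tab$gene), c("GA", "GB"))
  expect_true(all(tab$ci_low <= tab$odds_ratio & tab$odds_ratio <= tab$ci_high))
  expect_true(all(tab$n_used == 40))
})

test_that("a duplicated predictor collapses to the univariate model", {
  set.seed(12)
  x <- rnorm(60)
  status <- ifelse(rbinom(60, 1, plogis(0.8 * x)) == 1, "POSITIVE", "NEGATIVE")
  d <- dct_ann(list(GA = x, GB = x), status)
  expect_warning(m <- multivariate_model(d$dct, d$ann, c("GA", "GB")),
                 "collinear")
  uni_auc <- roc_auc(tibble::tibble(risk_score = x, ln_status = status))$auc
  expect_equal(m$roc$auc, uni_auc, tolerance = 1e-12)
  expect_true(any(is.na(tidy(m)$estimate)) || nrow(tidy(m)) == 2)
})

test_that("two informative predictors beat each alone on average", {
  set.seed(17)
  deltas <- replicate(30, {
    n <- 200
    x1 <- rnorm(n)
    x2 <- rnorm(n)
    status <- ifelse(rbinom(n, 1, plogis(0.7 * x1 + 0.7 * x2)) == 1,
                     "POSITIVE", "NEGATIVE")
    if (length(unique(status)) < 2) return(NA)
    d <- dct_ann(list(GA = x1, GB = x2), status)
    m <- multivariate_model(d$dct, d$ann, c("GA", "GB"))
    a1 <- roc_auc(tibble::tibble(risk_score = x1, ln_status = status))$auc
    a2 <- roc_auc(tibble::tibble(risk_score = x2, ln_status = status))$auc
    m$roc$auc - max(a1, a2)
  })
  expect_gt(mean(deltas, na.rm = TRUE), 0)
})

test_that("null multivariate models center near AUC 0.5", {
  # in-sample AUC of a fitted model carries a small optimism; at n = 400
  # with two null predictors it stays close to chance
  set.seed(21)
  aucs <- replicate(30, {
    n <- 400
    status <- rep(c("POSITIVE", "NEGATIVE"), n / 2)
    d <- dct_ann(list(GA = rnorm(n), GB = rnorm(n)), status)
    multivariate_model(d$dct, d$ann, c("GA", "GB"))$roc$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.04)
})
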