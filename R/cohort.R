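#' Cohort characteristics table comparing LN-positive and LN-negative groups
#'
#' Builds a descriptive comparison table (one block per covariate) in the
#' style of a clinical "Table 1". Categorical covariates get per-level counts
#' and percentages of the full group size (including an explicit `Unknown`
#' level, shown but excluded from testing), with Fisher's exact test for
#' 2x2 known-level tables and a chi-square test otherwise. Numeric
#' covariates get mean and range per group and a two-sided Mann-Whitney U
#' test. Percentages are rounded half away from zero to integers.
#'
#' @param annotation Annotation tibble (`sample_id`, `ln_status`, covariate
#'   columns). Samples with missing `ln_status` are excluded.
#' @param covariates Covariate column names (default: every column other
#'   than `sample_id` and `ln_status`).
#' @param unknown Level name treated as unknown in categorical covariates
#'   (default `"Unknown"`; `NA` is always treated as unknown).
#' @return A tibble with columns `covariate`, `type`, `level`, `n_neg`,
#'   `pct_neg`, `n_pos`, `pct_pos`, `summary_neg`, `summary_pos`, `test`,
#'   `statistic`, `p_value`. For categorical covariates `test`/`p_value`
#'   are repeated on each level row.
#' @export
cohort_compare <- function(annotation, covariates = NULL, unknown = "Unknown") {
  assert_columns(annotation, c("sample_id", "ln_status"), what = "annotation")
  ann <- dplyr::filter(annotation, !is.na(.data$ln_status))
  covariates <- covariates %||% setdiff(names(ann), c("sample_id", "ln_status"))
  n_neg_tot <- sum(ann$ln_status == "NEGATIVE")
  n_pos_tot <- sum(ann$ln_status == "POSITIVE")
  purrr::map_dfr(covariates, function(v) {
    x <- ann[[v]]
    if (is.numeric(x)) {
      cohort_row_numeric(v, x, ann$ln_status)
    } else {
      cohort_rows_categorical(v, as.character(x), ann$ln_status,
                              n_neg_tot, n_pos_tot, unknown)
    }
  })
}

cohort_row_numeric <- function(v, x, status) {
  xn <- x[status == "NEGATIVE"]
  xp <- x[status == "POSITIVE"]
  fmt <- function(z) {
    z <- z[!is.na(z)]
    if (length(z) == 0) return(NA_character_)
    sprintf("%.3g (%.3g-%.3g)", mean(z), min(z), max(z))
  }
  ok <- sum(!is.na(xn)) >= 1 && sum(!is.na(xp)) >= 1
  if (ok) {
    mw <- mann_whitney(xn[!is.na(xn)], xp[!is.na(xp)])
    stat <- mw$u_statistic
    p <- mw$p_value
    test <- "Mann-Whitney U"
  } else {
    stat <- NA_real_
    p <- NA_real_
    test <- NA_character_
  }
  tibble::tibble(covariate = v, type = "continuous", level = "mean (range)",
                 n_neg = sum(!is.na(xn)), pct_neg = NA_real_,
                 n_pos = sum(!is.na(xp)), pct_pos = NA_real_,
                 summary_neg = fmt(xn), summary_pos = fmt(xp),
                 test = test, statistic = stat, p_value = p)
}

cohort_rows_categorical <- function(v, x, status, n_neg_tot, n_pos_tot,
                                    unknown) {
  x[is.na(x) | x == ""] <- unknown
  levels_known <- sort(setdiff(unique(x), unknown))
  levels_all <- c(levels_known, if (unknown %in% x) unknown)
  # test on known levels only
  known <- x != unknown
  test <- NA_character_
  stat <- NA_real_
  p <- NA_real_
  if (length(levels_known) >= 2 && sum(known) > 0) {
    tab <- table(factor(x[known], levels = levels_known), status[known])
    if (all(dim(tab) == c(2, 2)) && all(rowSums(tab) > 0) &&
        all(colSums(tab) > 0)) {
      ft <- stats::fisher.test(tab)
      test <- "Fisher exact"
      p <- ft$p.value
    } else if (all(colSums(tab) > 0)) {
      ct <- suppressWarnings(stats::chisq.test(tab))
      test <- "chi-square"
      stat <- unname(ct$statistic)
      p <- ct$p.value
    }
  }
  purrr::map_dfr(levels_all, function(lev) {
    n_neg <- sum(x == lev & status == "NEGATIVE")
    n_pos <- sum(x == lev & status == "POSITIVE")
    tibble::tibble(
      covariate = v, type = "categorical", level = lev,
      n_neg = n_neg,
      pct_neg = round_half_up(100 * n_neg / n_neg_tot),
      n_pos = n_pos,
      pct_pos = round_half_up(100 * n_pos / n_pos_tot),
      summary_neg = NA_character_, summary_pos = NA_character_,
      test = test, statistic = stat, p_value = p)
  })
}
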