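#' Two-sided Mann-Whitney U test
#'
#' The U statistic is reported for the first group `x`: the number of pairs
#' `(x_i, y_j)` with `x_i > y_j`, counting ties as 1/2. The two-sided
#' p-value is exact — obtained by complete enumeration of all
#' `choose(n1 + n2, n1)` group assignments, counting assignments whose U is
#' at least as far from the null mean `n1 n2 / 2` as the observed U —
#' whenever the number of assignments is at most `max_enum`; otherwise a
#' tie-corrected normal approximation (no continuity correction) is used.
#' The exact path is valid in the presence of ties.
#'
#' @param x,y Numeric vectors (the two groups).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` (default) decides by `max_enum`.
#' @param max_enum Maximum number of assignments enumerated exactly
#'   (default 1e5).
#' @return A one-row tibble: `u_statistic`, `p_value`, `method`, `n1`, `n2`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mann_whitney <- function(x, y, exact = NULL, max_enum = 1e5) {
  x <- as.numeric(x[!is.na(x)])
  y <- as.numeric(y[!is.na(y)])
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) abort("both groups need at least one value")
  comb <- c(x, y)
  r <- rank(comb)  # midranks
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n_assign <- choose(n1 + n2, n1)
  do_exact <- exact %||% (n_assign <= max_enum)
  if (isTRUE(exact) && n_assign > max_enum) {
    warn(sprintf("exact enumeration over %.0f assignments requested; this may be slow",
                 n_assign))
  }
  if (do_exact) {
    idx <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    N <- n1 + n2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      warn("all values tied across both groups; p = 1")
      p <- 1
      method <- "degenerate (all tied)"
    } else {
      zstat <- (u_obs - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(zstat)))
      method <- "normal approximation (tie-corrected)"
    }
  }
  tibble::tibble(u_statistic = u_obs, p_value = p, method = method,
                 n1 = n1, n2 = n2)
}

#' Two-group test of an expression value (data-frame interface)
#'
#' Splits `data` by a two-level grouping column and runs [mann_whitney()],
#' reporting U for the group named by `first` (default: the first sorted
#' level).
#'
#' @param data A data frame.
#' @param value Column holding the measured value (tidy-evaluated).
#' @param group Column holding the group label (must have exactly 2
#'   non-missing levels).
#' @param first Which level counts as the first group for the U convention.
#' @param ... Passed to [mann_whitney()].
#' @return One-row tibble as in [mann_whitney()], plus `group1`, `group2`.
#' @export
two_group_test <- function(data, value, group, first = NULL, ...) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- as.character(g[keep])
  lev <- sort(unique(g))
  if (length(lev) != 2) {
    abort(sprintf("`group` must have exactly 2 levels, found %d", length(lev)))
  }
  first <- first %||% lev[1]
  if (!first %in% lev) abort(sprintf("level '%s' not present", first))
  second <- setdiff(lev, first)
  res <- mann_whitney(v[g == first], v[g == second], ...)
  res$group1 <- first
  res$group2 <- second
  res
}

#' Per-gene two-group tests on an external expression cohort
#'
#' Runs a two-sided Mann-Whitney test per signature gene comparing
#' lymph-node-positive against lymph-node-negative samples of an external
#' expression matrix (e.g. an RNA-seq cohort export). U is reported for the
#' positive group.
#'
#' @param expr Long expression tibble (`gene`, `sample_id`, `expression`),
#'   e.g. from [read_expression_matrix()] or
#'   [simulate_expression_cohort()].
#' @param groups Tibble with `sample_id` and `group`.
#' @param genes Genes to test (default: all genes in `expr`).
#' @param positive Group level treated as positive (default `"POSITIVE"`).
#' @param ... Passed to [mann_whitney()].
#' @return A tibble with one row per gene: `gene`, `u_statistic`,
#'   `p_value`, `method`, `n_pos`, `n_neg`.
#' @export
compare_cohort <- function(expr, groups, genes = NULL,
                           positive = "POSITIVE", ...) {
  assert_columns(expr, c("gene", "sample_id", "expression"),
                 what = "expression table")
  assert_columns(groups, c("sample_id", "group"), what = "group table")
  genes <- genes %||% unique(expr$gene)
  joined <- expr |>
    dplyr::inner_join(groups, by = "sample_id") |>
    dplyr::filter(!is.na(.data$expression), !is.na(.data$group))
  purrr::map_dfr(genes, function(g) {
    d <- dplyr::filter(joined, .data$gene == g)
    pos <- d$expression[d$group == positive]
    neg <- d$expression[d$group != positive]
    if (length(pos) == 0 || length(neg) == 0) {
      return(tibble::tibble(gene = g, u_statistic = NA_real_,
                            p_value = NA_real_, method = "missing group",
                            n_pos = length(pos), n_neg = length(neg)))
    }
    res <- mann_whitney(pos, neg, ...)
    tibble::tibble(gene = g, u_statistic = res$u_statistic,
                   p_value = res$p_value, method = res$method,
                   n_pos = res$n1, n_neg = res$n2)
  })
}
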