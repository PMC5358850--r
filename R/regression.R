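#' Per-gene univariate logistic odds ratios
#'
#' For each gene, fits a maximum-likelihood logistic regression of lymph-node
#' status (positive = 1) on the gene's delta-Ct and reports the per-cycle
#' odds ratio `exp(beta)` with a Wald 95% confidence interval and p-value.
#'
#' Complete separation is flagged (infinite interval, not an error); a
#' constant predictor yields an `NA` row with a note.
#'
#' @param dct Long delta-Ct tibble from [compute_delta_ct()].
#' @param annotation Annotation tibble with `sample_id`, `ln_status`.
#' @param genes Genes to fit (default: every gene in `dct`).
#' @param conf_level Confidence level for the Wald interval (default 0.95).
#' @return A tibble with one row per gene: `gene`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `n_used`, `note`.
#' @export
univariate_or <- function(dct, annotation, genes = NULL, conf_level = 0.95) {
  assert_columns(dct, c("sample_id", "gene", "delta_ct"), what = "delta-Ct table")
  assert_columns(annotation, c("sample_id", "ln_status"), what = "annotation")
  genes <- genes %||% unique(dct$gene)
  joined <- dct |>
    dplyr::inner_join(dplyr::select(annotation, "sample_id", "ln_status"),
                      by = "sample_id") |>
    dplyr::filter(!is.na(.data$delta_ct), !is.na(.data$ln_status))
  purrr::map_dfr(genes, function(g) {
    d <- dplyr::filter(joined, .data$gene == g)
    y <- as.integer(d$ln_status == "POSITIVE")
    x <- d$delta_ct
    n <- length(y)
    empty <- tibble::tibble(gene = g, odds_ratio = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, p_value = NA_real_,
                            n_used = n, note = NA_character_)
    if (sum(y == 1) < 2 || sum(y == 0) < 2) {
      empty$note <- "fewer than 2 samples per group"
      return(empty)
    }
    if (length(unique(x)) == 1) {
      empty$note <- "constant predictor"
      return(empty)
    }
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ x, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          sep <<- TRUE
        }
        invokeRestart("muffleWarning")
      }
    )
    sm <- summary(fit)$coefficients
    beta <- sm["x", "Estimate"]
    se <- sm["x", "Std. Error"]
    p <- sm["x", "Pr(>|z|)"]
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    if (sep || abs(beta) > 15) {
      tibble::tibble(gene = g, odds_ratio = exp(beta), ci_low = 0,
                     ci_high = Inf, p_value = p, n_used = n,
                     note = "possible complete separation")
    } else {
      tibble::tibble(gene = g, odds_ratio = exp(beta),
                     ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
                     p_value = p, n_used = n, note = NA_character_)
    }
  })
}

#' Multivariate logistic model over several genes with in-sample ROC
#'
#' Fits one logistic regression of lymph-node status on the delta-Ct values
#' of several genes jointly (complete cases only) and evaluates the
#' discrimination of the fitted linear predictor by an in-sample ROC curve
#' (no cross-validation). Perfectly collinear predictors are dropped by the
#' fit with a warning.
#'
#' @inheritParams univariate_or
#' @param genes Genes to include as joint predictors.
#' @param ci_method Passed to [roc_auc()] for the AUC interval.
#' @return An object of class `nodesig_logistic`: list with `coefficients`
#'   (tibble `term`, `estimate`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`), `roc` (a `nodesig_roc`), `n_used`, `genes`.
#' @export
multivariate_model <- function(dct, annotation, genes,
                               conf_level = 0.95,
                               ci_method = c("delong", "bootstrap")) {
  ci_method <- match.arg(ci_method)
  assert_columns(dct, c("sample_id", "gene", "delta_ct"), what = "delta-Ct table")
  wide <- dct |>
    dplyr::filter(.data$gene %in% genes) |>
    dplyr::select("sample_id", "gene", "delta_ct") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "delta_ct") |>
    dplyr::inner_join(dplyr::select(annotation, "sample_id", "ln_status"),
                      by = "sample_id") |>
    dplyr::filter(!is.na(.data$ln_status)) |>
    tidyr::drop_na(dplyr::any_of(genes))
  if (nrow(wide) == 0) abort("no complete-case samples for the requested genes")
  y <- as.integer(wide$ln_status == "POSITIVE")
  X <- as.data.frame(wide[, genes, drop = FALSE])
  fit <- suppressWarnings(stats::glm(y ~ ., data = cbind(y = y, X),
                                     family = stats::binomial()))
  cf <- coef(fit)
  if (anyNA(cf)) {
    warn(sprintf("collinear predictor(s) dropped from the fit: %s",
                 paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    odds_ratio = exp(sm[, "Estimate"]),
    ci_low = exp(sm[, "Estimate"] - z * sm[, "Std. Error"]),
    ci_high = exp(sm[, "Estimate"] + z * sm[, "Std. Error"]),
    p_value = sm[, "Pr(>|z|)"]
  )
  lp <- as.numeric(predict(fit, type = "link"))
  roc <- roc_auc(tibble::tibble(risk_score = lp,
                                ln_status = wide$ln_status),
                 ci_method = ci_method, conf_level = conf_level)
  structure(list(coefficients = coefs, roc = roc, n_used = nrow(wide),
                 genes = genes),
            class = "nodesig_logistic")
}

#' @export
print.nodesig_logistic <- function(x, ...) {
  cat(sprintf("<nodesig_logistic> %d predictor gene(s), n = %d\n",
              length(x$genes), x$n_used))
  print(x$roc)
  invisible(x)
}

#' @describeIn multivariate_model Coefficient table.
#' @param x A `nodesig_logistic` object.
#' @param ... Unused.
#' @export
tidy.nodesig_logistic <- function(x, ...) x$coefficients

#' @describeIn multivariate_model One-row model summary with in-sample AUC.
#' @export
glance.nodesig_logistic <- function(x, ...) {
  g <- glance(x$roc)
  g$n_used <- x$n_used
  g
}
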