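#' ROC curve and AUC with confidence interval for a risk score
#'
#' Evaluates how well a continuous score discriminates lymph-node-positive
#' from lymph-node-negative samples. The AUC uses the standard half-credit
#' convention for ties (equivalent to the normalized Mann-Whitney U
#' statistic); the orientation is fixed so that higher scores predicting the
#' positive class gives AUC > 0.5 (no automatic direction flipping, so a
#' score performing worse than chance yields AUC < 0.5). The confidence
#' interval is DeLong's (default) or a stratified bootstrap.
#'
#' @param data A data frame with one row per sample.
#' @param score Column holding the score (tidy-evaluated; default
#'   `risk_score`).
#' @param truth Column holding the class label (default `ln_status`).
#' @param positive Value of `truth` treated as the positive class
#'   (default `"POSITIVE"`); all other non-missing values are negatives.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param boot_n Bootstrap draws when `ci_method = "bootstrap"` (default
#'   2000); seed the session for reproducibility.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `nodesig_roc`: list with `auc`, `ci_low`,
#'   `ci_high`, `n_pos`, `n_neg`, `curve` (tibble `threshold`, `fpr`,
#'   `tpr`), `ci_method`, `conf_level`, `degenerate`, `n_dropped`.
#'   Rows with missing score or label are dropped and counted.
#' @export
#' @examples
#' d <- tibble::tibble(risk_score = c(2, 3, 0, 1),
#'                     ln_status = c("POSITIVE", "POSITIVE", "NEGATIVE", "NEGATIVE"))
#' roc_auc(d)$auc  # 1: perfect separation
roc_auc <- function(data, score = NULL, truth = NULL, positive = "POSITIVE",
                    ci_method = c("delong", "bootstrap"), boot_n = 2000,
                    conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  score_q <- rlang::enquo(score)
  truth_q <- rlang::enquo(truth)
  s <- if (rlang::quo_is_null(score_q)) data[["risk_score"]]
       else rlang::eval_tidy(score_q, data)
  lbl <- if (rlang::quo_is_null(truth_q)) data[["ln_status"]]
         else rlang::eval_tidy(truth_q, data)
  if (is.null(s) || is.null(lbl)) {
    abort("`data` must supply score and truth columns (default risk_score, ln_status)")
  }
  keep <- !is.na(s) & !is.na(lbl)
  n_dropped <- sum(!keep)
  s <- as.numeric(s[keep])
  y <- as.integer(lbl[keep] == positive)
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present to compute a ROC curve")
  }

  if (length(unique(s)) == 1) {
    # constant score: no discrimination, interval degenerate
    res <- list(auc = 0.5, ci_low = NA_real_, ci_high = NA_real_,
                n_pos = n_pos, n_neg = n_neg,
                curve = tibble::tibble(threshold = c(Inf, -Inf),
                                       fpr = c(0, 1), tpr = c(0, 1)),
                ci_method = ci_method, conf_level = conf_level,
                degenerate = TRUE, n_dropped = n_dropped)
    return(structure(res, class = "nodesig_roc"))
  }

  r <- pROC::roc(response = y, predictor = s, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- if (ci_method == "delong") {
    suppressWarnings(pROC::ci.auc(r, conf.level = conf_level, method = "delong"))
  } else {
    suppressWarnings(pROC::ci.auc(r, conf.level = conf_level,
                                  method = "bootstrap", boot.n = boot_n,
                                  boot.stratified = TRUE, progress = "none"))
  }
  curve <- tibble::tibble(
    threshold = r$thresholds,
    fpr = 1 - r$specificities,
    tpr = r$sensitivities
  ) |> dplyr::arrange(.data$fpr, .data$tpr)
  res <- list(auc = auc,
              ci_low = max(0, as.numeric(ci[1])),
              ci_high = min(1, as.numeric(ci[3])),
              n_pos = n_pos, n_neg = n_neg, curve = curve,
              ci_method = ci_method, conf_level = conf_level,
              degenerate = FALSE, n_dropped = n_dropped)
  structure(res, class = "nodesig_roc")
}

#' @export
print.nodesig_roc <- function(x, ...) {
  cat(sprintf("<nodesig_roc> AUC = %.3f (%d%% CI %s-%s, %s), n = %d pos / %d neg\n",
              x$auc, round(100 * x$conf_level),
              ifelse(is.na(x$ci_low), "NA", sprintf("%.3f", x$ci_low)),
              ifelse(is.na(x$ci_high), "NA", sprintf("%.3f", x$ci_high)),
              x$ci_method, x$n_pos, x$n_neg))
  if (x$degenerate) cat("  (constant score: degenerate interval)\n")
  invisible(x)
}

#' @describeIn roc_auc Tidy the ROC curve points into a tibble.
#' @param x A `nodesig_roc` object.
#' @param ... Unused.
#' @export
tidy.nodesig_roc <- function(x, ...) x$curve

#' @describeIn roc_auc One-row summary (AUC, CI, group sizes).
#' @export
glance.nodesig_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
                 conf_level = x$conf_level, ci_method = x$ci_method,
                 n_pos = x$n_pos, n_neg = x$n_neg,
                 degenerate = x$degenerate)
}

#' @describeIn roc_auc ROC curve plot.
#' @param object A `nodesig_roc` object.
#' @export
autoplot.nodesig_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("AUC = %.2f (%d%% CI %.2f-%.2f)", object$auc,
                      round(100 * object$conf_level),
                      object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal()
}

#' Re-evaluate the ROC on a subgroup of samples
#'
#' Restricts the score table to the rows matching a filter predicate (for
#' example, samples from a single originating site) and recomputes
#' [roc_auc()] there.
#'
#' @param data Score table (one row per sample).
#' @param subset Filter expression evaluated in `data` (tidy-evaluated).
#' @param ... Passed to [roc_auc()].
#' @return A `nodesig_roc` for the subgroup.
#' @export
subgroup_evaluate <- function(data, subset, ...) {
  keep <- rlang::eval_tidy(rlang::enquo(subset), data)
  if (!is.logical(keep)) abort("`subset` must evaluate to a logical vector")
  sub <- data[!is.na(keep) & keep, , drop = FALSE]
  if (nrow(sub) == 0) abort("subgroup filter keeps no samples")
  roc_auc(sub, ...)
}
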