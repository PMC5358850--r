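#' Per-gene mean delta-Ct by lymph-node status
#'
#' Group means of the normalized expression per gene (the bar-plot summary
#' of the validation): mean, median and n per gene and LN group.
#'
#' @param dct Long delta-Ct tibble.
#' @param annotation Annotation tibble (`sample_id`, `ln_status`).
#' @return Tibble `gene`, `ln_status`, `n`, `mean_delta_ct`,
#'   `median_delta_ct`, `sd_delta_ct`.
#' @export
gene_group_means <- function(dct, annotation) {
  dct |>
    dplyr::inner_join(dplyr::select(annotation, "sample_id", "ln_status"),
                      by = "sample_id") |>
    dplyr::filter(!is.na(.data$delta_ct), !is.na(.data$ln_status)) |>
    dplyr::group_by(.data$gene, .data$ln_status) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_delta_ct = mean(.data$delta_ct),
                     median_delta_ct = stats::median(.data$delta_ct),
                     sd_delta_ct = stats::sd(.data$delta_ct),
                     .groups = "drop")
}

#' Run the full signature validation end-to-end
#'
#' Composes the whole analysis: replicate reconciliation, reliability
#' flagging, housekeeping-based sample discard, delta-Ct normalization, risk
#' scoring, ROC/AUC, per-gene univariate odds ratios, per-gene group means,
#' correlation clustering, a cohort characteristics table (when the
#' annotation carries covariates), and optionally per-gene two-group tests
#' on an external expression cohort.
#'
#' Samples without a lymph-node status are QC'd and normalized but excluded
#' from all statistics; the attrition summary accounts for every input
#' sample (`analyzed + discarded + no annotation = input`).
#'
#' @param ct Ct table ([read_ct_table()] format) or a path to one.
#' @param annotation Annotation tibble or path.
#' @param sig A [signature_definition()] or path to a config file.
#' @param multiplier Reliability-interval half-width in SDs (default 1.96).
#' @param min_genes Minimum usable genes per direction for scoring.
#' @param ci_method `"delong"` or `"bootstrap"` for AUC intervals.
#' @param cut_height Cluster cut height on the 1 - r scale (default 0.34).
#' @param external Optional external expression cohort: a list with
#'   `expression` and `groups` as from [read_expression_matrix()] or
#'   [simulate_expression_cohort()].
#' @param include_unreliable,ceiling_policy Passed to [compute_delta_ct()].
#' @return An object of class `evaluation_report`: list with `qc`
#'   (attrition and flag counts), `delta_ct`, `risk_scores`, `roc`
#'   (`nodesig_roc`), `or_table`, `gene_means`, `correlation`
#'   (`nodesig_corr` or `NULL`), `cohort_table` (or `NULL`),
#'   `external_tests` (or `NULL`), and `params`.
#' @export
run_validation <- function(ct, annotation, sig = default_signature(),
                           multiplier = 1.96, min_genes = 1,
                           ci_method = c("delong", "bootstrap"),
                           cut_height = 0.34, external = NULL,
                           include_unreliable = FALSE,
                           ceiling_policy = c("retain", "missing")) {
  ci_method <- match.arg(ci_method)
  ceiling_policy <- match.arg(ceiling_policy)
  if (is.character(ct)) ct <- read_ct_table(ct)
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  if (is.character(sig)) sig <- read_signature_config(sig)
  annotation <- validate_annotation(annotation)
  if (!is.null(sig$plate_control)) {
    ct <- dplyr::filter(ct, .data$sample_id != sig$plate_control)
  }

  qc_tbl <- ct |>
    reconcile_replicates(sig) |>
    flag_unreliable(multiplier = multiplier) |>
    discard_samples(sig)
  qcs <- qc_summary(qc_tbl)

  dct <- compute_delta_ct(qc_tbl, sig,
                          include_unreliable = include_unreliable,
                          ceiling_policy = ceiling_policy)

  annotated <- annotation$sample_id[!is.na(annotation$ln_status)]
  input_samples <- unique(ct$sample_id)
  discarded <- qcs$discards$sample_id
  no_annotation <- setdiff(setdiff(input_samples, discarded), annotated)
  analyzed <- setdiff(intersect(input_samples, annotated), discarded)

  scores <- compute_risk_score(dct, sig, annotation = annotation,
                               min_genes = min_genes) |>
    dplyr::filter(.data$sample_id %in% analyzed)
  roc <- roc_auc(scores, ci_method = ci_method)

  dct_analyzed <- dplyr::filter(dct, .data$sample_id %in% analyzed)
  scored_genes <- intersect(sig$genes, unique(dct_analyzed$gene))
  or_table <- univariate_or(dct_analyzed, annotation, genes = scored_genes)
  gene_means <- gene_group_means(dct_analyzed, annotation)

  correlation <- tryCatch(
    correlation_cluster(
      dplyr::filter(dct_analyzed, .data$gene %in% scored_genes),
      cut_height = cut_height),
    error = function(e) NULL)

  covars <- setdiff(names(annotation), c("sample_id", "ln_status"))
  cohort_table <- if (length(covars) > 0) {
    cohort_compare(dplyr::filter(annotation, .data$sample_id %in% analyzed))
  } else NULL

  external_tests <- if (!is.null(external)) {
    compare_cohort(external$expression, external$groups,
                   genes = intersect(sig$genes,
                                     unique(external$expression$gene)))
  } else NULL

  qc <- list(
    n_input_samples = length(input_samples),
    n_analyzed = length(analyzed),
    n_discarded = length(discarded),
    n_no_annotation = length(no_annotation),
    flag_counts = qcs$flag_counts,
    discards = qcs$discards
  )
  stopifnot(qc$n_input_samples == qc$n_analyzed + qc$n_discarded +
              qc$n_no_annotation)

  structure(list(qc = qc, delta_ct = dct, risk_scores = scores, roc = roc,
                 or_table = or_table, gene_means = gene_means,
                 correlation = correlation, cohort_table = cohort_table,
                 external_tests = external_tests,
                 params = list(multiplier = multiplier, min_genes = min_genes,
                               ci_method = ci_method, cut_height = cut_height,
                               include_unreliable = include_unreliable,
                               ceiling_policy = ceiling_policy,
                               ct_ceiling = sig$ct_ceiling)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  samples: %d input = %d analyzed + %d discarded + %d without annotation\n",
              x$qc$n_input_samples, x$qc$n_analyzed, x$qc$n_discarded,
              x$qc$n_no_annotation))
  print(x$roc)
  best <- x$or_table[order(x$or_table$p_value), ][1, ]
  if (nrow(x$or_table) > 0 && !is.na(best$odds_ratio)) {
    cat(sprintf("  best single gene: %s OR %.2f (%.2f-%.2f), p = %.2g\n",
                best$gene, best$odds_ratio, best$ci_low, best$ci_high,
                best$p_value))
  }
  invisible(x)
}

#' Write an evaluation report to delimited-text files
#'
#' Writes the report's tables as CSV (risk scores, OR table, gene means,
#' correlation matrix, cohort table, external tests, QC flags/discards) plus
#' a machine-readable `summary.json`. Column order is fixed; output is
#' deterministic, so writing the same report twice yields byte-identical
#' files.
#'
#' @param report An `evaluation_report` from [run_validation()].
#' @param outdir Output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir)) {
      abort(sprintf("cannot create output directory '%s'", outdir))
    }
  }
  files <- character()
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    readr::write_csv(df, p, progress = FALSE)
    files <<- c(files, p)
  }
  wr(report$risk_scores, "risk_scores.csv")
  wr(report$or_table, "odds_ratios.csv")
  wr(report$gene_means, "gene_group_means.csv")
  wr(tidy(report$roc), "roc_curve.csv")
  wr(report$qc$flag_counts, "qc_flag_counts.csv")
  wr(report$qc$discards, "qc_discards.csv")
  if (!is.null(report$correlation)) {
    rmat <- report$correlation$r
    rdf <- tibble::as_tibble(rmat, rownames = "gene")
    wr(rdf, "correlation_matrix.csv")
    wr(tibble::tibble(gene = names(report$correlation$clusters),
                      cluster = unname(report$correlation$clusters)),
       "clusters.csv")
  }
  if (!is.null(report$cohort_table)) wr(report$cohort_table, "cohort_table.csv")
  if (!is.null(report$external_tests)) {
    wr(report$external_tests, "external_tests.csv")
  }
  summary <- list(
    auc = report$roc$auc, ci_low = report$roc$ci_low,
    ci_high = report$roc$ci_high, ci_method = report$roc$ci_method,
    n_pos = report$roc$n_pos, n_neg = report$roc$n_neg,
    n_input_samples = report$qc$n_input_samples,
    n_analyzed = report$qc$n_analyzed,
    n_discarded = report$qc$n_discarded,
    n_no_annotation = report$qc$n_no_annotation,
    params = report$params
  )
  p <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, p)
  invisible(files)
}

#' Run the simulate-to-ROC pipeline on one synthetic cohort
#'
#' Convenience wrapper used heavily in calibration studies: simulates a
#' cohort from `cfg`, runs QC, normalization and scoring, and returns the
#' ROC of the risk score.
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed.
#' @param ... Passed to [roc_auc()].
#' @return A `nodesig_roc`.
#' @export
simulate_and_evaluate <- function(cfg, seed = 1, ...) {
  sim <- simulate_ct_cohort(cfg, seed = seed)
  qc <- sim$ct |>
    reconcile_replicates(cfg$signature) |>
    flag_unreliable() |>
    discard_samples(cfg$signature)
  dct <- compute_delta_ct(qc, cfg$signature)
  scores <- compute_risk_score(dct, cfg$signature, annotation = sim$annotation)
  roc_auc(scores, ...)
}
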