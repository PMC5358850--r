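#' Compute the per-sample signature risk score
#'
#' The risk score of a sample is the mean delta-Ct of the signature genes
#' down-regulated in lymph-node-positive tumors minus the mean delta-Ct of
#' the genes up-regulated in LN+ tumors. Because delta-Ct is inversely
#' related to expression, higher expression of up-regulated genes (lower
#' delta-Ct) increases the score, so higher scores indicate an
#' LN+-like expression pattern.
#'
#' Genes with missing delta-Ct for a sample are dropped from their direction
#' mean; a sample with fewer than `min_genes` usable genes in either
#' direction gets an `NA` score with a reason. Signature genes with
#' `"unspecified"` direction cannot be placed in either mean and are ignored
#' with a warning.
#'
#' @param dct Long delta-Ct tibble from [compute_delta_ct()].
#' @param sig A [signature_definition()] whose direction labels define the
#'   up/down gene sets (both must be non-empty).
#' @param annotation Optional clinical annotation tibble (`sample_id`,
#'   `ln_status`) joined onto the result.
#' @param min_genes Minimum usable genes required per direction (default 1);
#'   set to the full direction sizes for a strict all-genes policy.
#' @return A tibble with columns `sample_id`, `risk_score`,
#'   `n_down_genes_used`, `n_up_genes_used`, `note` and, when `annotation`
#'   is given, `ln_status`.
#' @export
#' @examples
#' sig <- signature_definition(c("D1", "D2", "U1", "U2"),
#'   direction = c(D1 = "down", D2 = "down", U1 = "up", U2 = "up"))
#' dct <- tibble::tibble(
#'   sample_id = "S1", gene = c("D1", "D2", "U1", "U2"),
#'   delta_ct = c(5, 7, 2, 4))
#' compute_risk_score(dct, sig)  # (6) - (3) = 3
compute_risk_score <- function(dct, sig, annotation = NULL, min_genes = 1) {
  assert_columns(dct, c("sample_id", "gene", "delta_ct"), what = "delta-Ct table")
  stopifnot(inherits(sig, "signature_definition"))
  up <- direction_genes(sig, "up")
  down <- direction_genes(sig, "down")
  if (length(up) == 0 || length(down) == 0) {
    abort("signature must have at least one gene in each direction (up and down)")
  }
  unspec <- direction_genes(sig, "unspecified")
  if (length(unspec) > 0) {
    warn(sprintf("%d signature gene(s) with unspecified direction excluded from the score: %s",
                 length(unspec), paste(unspec, collapse = ", ")))
  }
  out <- dct |>
    dplyr::filter(.data$gene %in% c(up, down), !is.na(.data$delta_ct)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_down_genes_used = sum(.data$gene %in% down),
      n_up_genes_used = sum(.data$gene %in% up),
      .down_mean = mean(.data$delta_ct[.data$gene %in% down]),
      .up_mean = mean(.data$delta_ct[.data$gene %in% up]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      risk_score = ifelse(.data$n_down_genes_used >= min_genes &
                            .data$n_up_genes_used >= min_genes,
                          .data$.down_mean - .data$.up_mean, NA_real_),
      note = ifelse(is.na(.data$risk_score),
                    sprintf("fewer than %d usable genes in a direction group", min_genes),
                    NA_character_)
    ) |>
    dplyr::select("sample_id", "risk_score",
                  "n_down_genes_used", "n_up_genes_used", "note")
  # samples present in dct but with no scoreable gene at all
  missing_samples <- setdiff(unique(dct$sample_id), out$sample_id)
  if (length(missing_samples) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      sample_id = missing_samples, risk_score = NA_real_,
      n_down_genes_used = 0L, n_up_genes_used = 0L,
      note = "no usable signature genes"))
  }
  out <- dplyr::arrange(out, .data$sample_id)
  if (!is.null(annotation)) {
    out <- dplyr::left_join(out,
                            dplyr::select(annotation, "sample_id", "ln_status"),
                            by = "sample_id")
  }
  out
}
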