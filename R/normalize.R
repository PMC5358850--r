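#' Compute delta-Ct values normalized over the reference gene(s)
#'
#' Collapses usable replicate Ct values to one value per (sample, gene) and
#' subtracts the sample's mean reference-gene Ct (default reference: ACTB),
#' yielding delta-Ct in cycles. Higher delta-Ct means lower expression
#' relative to the reference.
#'
#' Usable values exclude `unreliable` measurements by default;
#' `ceiling_undetermined` values (set to the Ct ceiling) are retained by
#' default and can be treated as missing with `ceiling_policy = "missing"`.
#' Samples flagged discarded are dropped. Cells with no usable replicate are
#' explicit `NA` rows.
#'
#' @param tbl QC-annotated table (after [discard_samples()]; a table without
#'   discard columns is treated as all-retained).
#' @param sig A [signature_definition()] supplying the reference gene set.
#' @param collapse `"mean"` (default) collapses replicates by their
#'   arithmetic mean; `"keep_all"` returns one row per usable replicate
#'   (for duplicate-concordance checks).
#' @param include_unreliable Include `unreliable` values in collapsing
#'   (default `FALSE`).
#' @param ceiling_policy `"retain"` (default) keeps ceiling substitutions as
#'   measurements; `"missing"` drops them.
#' @return A long tibble with columns `sample_id`, `gene`, `delta_ct`,
#'   `n_replicates_used`, `ref_ct_mean` (plus `replicate` when
#'   `collapse = "keep_all"`). Reference genes themselves are not reported.
#'   The reference gene set and policies are stored in attributes.
#' @export
compute_delta_ct <- function(tbl, sig,
                             collapse = c("mean", "keep_all"),
                             include_unreliable = FALSE,
                             ceiling_policy = c("retain", "missing")) {
  collapse <- match.arg(collapse)
  ceiling_policy <- match.arg(ceiling_policy)
  assert_columns(tbl, c("sample_id", "gene", "replicate", "ct", "status"),
                 what = "QC-annotated table")
  stopifnot(inherits(sig, "signature_definition"))
  if ("sample_discarded" %in% names(tbl)) {
    tbl <- dplyr::filter(tbl, !.data$sample_discarded)
  }
  usable <- rep(TRUE, nrow(tbl))
  if (!include_unreliable) usable <- usable & tbl$status != "unreliable"
  if (ceiling_policy == "missing") {
    usable <- usable & tbl$status != "ceiling_undetermined"
  }
  tbl$.usable <- usable

  refs <- tbl |>
    dplyr::filter(.data$gene %in% sig$reference_genes, .data$.usable) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(ref_ct_mean = mean(.data$ct), .groups = "drop")
  no_ref <- setdiff(unique(tbl$sample_id), refs$sample_id)
  if (length(no_ref) > 0) {
    warn(sprintf("sample(s) with no usable reference-gene value excluded from delta-Ct: %s",
                 paste(no_ref, collapse = ", ")))
  }

  genes_tbl <- tbl |>
    dplyr::filter(!.data$gene %in% sig$reference_genes) |>
    dplyr::inner_join(refs, by = "sample_id")

  out <- if (collapse == "mean") {
    # vectorized collapse: mean of usable replicates per (sample, gene)
    kf <- factor(paste(genes_tbl$sample_id, genes_tbl$gene, sep = "\r"))
    ki <- as.integer(kf)
    n_used_g <- as.vector(rowsum(as.numeric(genes_tbl$.usable), ki))
    sum_ct_g <- as.vector(rowsum(ifelse(genes_tbl$.usable, genes_tbl$ct, 0), ki))
    first <- !duplicated(ki)
    cell <- genes_tbl[first, c("sample_id", "gene", "ref_ct_mean")]
    kif <- ki[first]
    tibble::tibble(
      sample_id = cell$sample_id, gene = cell$gene,
      delta_ct = ifelse(n_used_g[kif] > 0,
                        sum_ct_g[kif] / pmax(n_used_g[kif], 1) - cell$ref_ct_mean,
                        NA_real_),
      n_replicates_used = as.integer(n_used_g[kif]),
      ref_ct_mean = cell$ref_ct_mean
    )
  } else {
    genes_tbl |>
      dplyr::filter(.data$.usable) |>
      dplyr::transmute(
        sample_id = .data$sample_id, gene = .data$gene,
        replicate = .data$replicate,
        delta_ct = .data$ct - .data$ref_ct_mean,
        n_replicates_used = 1L,
        ref_ct_mean = .data$ref_ct_mean
      )
  }
  out <- dplyr::arrange(out, .data$sample_id, .data$gene)
  attr(out, "reference_genes") <- sig$reference_genes
  attr(out, "delta_ct_params") <- list(collapse = collapse,
                                       include_unreliable = include_unreliable,
                                       ceiling_policy = ceiling_policy)
  out
}

#' Pivot a long delta-Ct table to a samples-by-genes matrix
#'
#' @param dct Long delta-Ct tibble from [compute_delta_ct()].
#' @return A numeric matrix, rows = samples, columns = genes, `NA` for
#'   missing cells.
#' @export
delta_ct_wide <- function(dct) {
  assert_columns(dct, c("sample_id", "gene", "delta_ct"), what = "delta-Ct table")
  wide <- dct |>
    dplyr::select("sample_id", "gene", "delta_ct") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "delta_ct")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m
}
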