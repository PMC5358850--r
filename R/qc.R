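#' Reconcile duplicate Ct measurements and resolve undetermined wells
#'
#' qPCR assays are run in duplicate; undetermined wells (no amplification
#' within the run's cycle limit) are resolved against their partner
#' replicate. If exactly one replicate of a (sample, gene) pair is
#' undetermined, it is set to the determined replicate's Ct and flagged
#' `imputed_from_replicate`. If all replicates are undetermined, every
#' replicate is set to the signature's Ct ceiling (default 35 cycles) and
#' flagged `ceiling_undetermined`. Determined values pass through as `ok`.
#'
#' @param tbl A Ct table from [read_ct_table()] (columns `sample_id`, `gene`,
#'   `replicate`, `plate_id`, `ct`, `undetermined`).
#' @param sig A [signature_definition()] supplying the Ct ceiling.
#' @param strict Error when a (sample, gene) pair has more than two
#'   replicates (default `TRUE`); with `FALSE` the same rules apply to the
#'   larger pool (undetermined wells take the mean of the determined ones).
#' @return A QC-annotated tibble: `undetermined` is replaced by a `status`
#'   column (`ok` / `imputed_from_replicate` / `ceiling_undetermined`), no
#'   `NA` Ct values remain. QC parameters are stored in the `qc_params`
#'   attribute.
#' @export
reconcile_replicates <- function(tbl, sig, strict = TRUE) {
  if ("status" %in% names(tbl) && !"undetermined" %in% names(tbl)) {
    # already reconciled: the operation is a no-op (idempotence)
    return(tbl)
  }
  validate_ct_table(tbl)
  stopifnot(inherits(sig, "signature_definition"))
  if (strict) {
    nrep <- dplyr::count(tbl, .data$sample_id, .data$gene)
    if (any(nrep$n > 2)) {
      bad <- nrep[nrep$n > 2, ][1, ]
      abort(sprintf("more than 2 replicates for (%s, %s); use strict = FALSE to allow",
                    bad$sample_id, bad$gene))
    }
  }
  # vectorized per-(sample, gene) reconciliation
  kf <- factor(paste(tbl$sample_id, tbl$gene, sep = "\r"))
  ki <- as.integer(kf)
  det <- !tbl$undetermined
  n_det_g <- as.vector(rowsum(as.numeric(det), ki))
  sum_det_g <- as.vector(rowsum(ifelse(det, tbl$ct, 0), ki))
  n_det <- n_det_g[ki]
  mean_det <- (sum_det_g / pmax(n_det_g, 1))[ki]
  out <- tbl
  out$status <- ifelse(det, "ok",
                       ifelse(n_det > 0, "imputed_from_replicate",
                              "ceiling_undetermined"))
  out$ct <- ifelse(det, tbl$ct, ifelse(n_det > 0, mean_det, sig$ct_ceiling))
  out$undetermined <- NULL
  attr(out, "qc_params") <- list(ct_ceiling = sig$ct_ceiling)
  out
}

#' Flag Ct values outside a per-transcript 95% interval as unreliable
#'
#' For each gene, the mean and standard deviation of its reconciled Ct values
#' are computed across all samples and replicates, excluding
#' `ceiling_undetermined` values (artificial ceiling substitutions, not
#' measurements). Values outside `mean +/- multiplier * sd` are flagged
#' `unreliable`; `multiplier = 1.96` corresponds to a 95% normal interval.
#' `ceiling_undetermined` values are never re-flagged. A gene with fewer
#' than three usable values is skipped with a warning. With `method =
#' "percentile"` the interval is instead the central `coverage` empirical
#' quantile range.
#'
#' When a gene's usable values are all identical (zero spread) the interval
#' degenerates to a point: equal values pass, any deviating value is flagged.
#'
#' @param tbl Output of [reconcile_replicates()].
#' @param multiplier Half-width of the interval in standard deviations
#'   (default 1.96).
#' @param method `"sd"` (mean +/- multiplier*sd) or `"percentile"`.
#' @param coverage Central coverage for the percentile method (default 0.95).
#' @return The table with `status` updated to `unreliable` where triggered.
#' @export
flag_unreliable <- function(tbl, multiplier = 1.96,
                            method = c("sd", "percentile"), coverage = 0.95) {
  method <- match.arg(method)
  assert_columns(tbl, c("sample_id", "gene", "ct", "status"),
                 what = "QC-annotated table")
  out <- tbl |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(.unrel = {
      usable <- .data$status != "ceiling_undetermined"
      x <- .data$ct[usable]
      if (sum(usable) < 3) {
        warn(sprintf("gene %s has fewer than 3 usable Ct values; reliability rule skipped",
                     .data$gene[1]))
        rep(FALSE, dplyr::n())
      } else if (method == "sd") {
        m <- mean(x)
        s <- stats::sd(x)
        usable & abs(.data$ct - m) > multiplier * s
      } else {
        q <- stats::quantile(x, c((1 - coverage) / 2, 1 - (1 - coverage) / 2),
                             names = FALSE, type = 7)
        usable & (.data$ct < q[1] | .data$ct > q[2])
      }
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(status = ifelse(.data$.unrel, "unreliable", .data$status)) |>
    dplyr::select(-".unrel")
  attr(out, "qc_params") <- c(attr(tbl, "qc_params"),
                              list(multiplier = multiplier, method = method))
  out
}

#' Discard samples with unreliable housekeeping measurements
#'
#' A sample is discarded when its housekeeping genes (default ACTB and HPRT,
#' replicate-level data points pooled across both genes) carry two or more
#' values flagged `ceiling_undetermined` or `unreliable`. A sample missing a
#' housekeeping gene entirely is discarded with reason
#' `"housekeeping absent"`. The discard reason lists the triggering data
#' points.
#'
#' @param tbl Output of [flag_unreliable()] (or [reconcile_replicates()]).
#' @param sig A [signature_definition()] supplying the housekeeping set.
#' @return The table with logical `sample_discarded` and character
#'   `discard_reason` columns added.
#' @export
discard_samples <- function(tbl, sig) {
  assert_columns(tbl, c("sample_id", "gene", "replicate", "ct", "status"),
                 what = "QC-annotated table")
  stopifnot(inherits(sig, "signature_definition"))
  hk <- sig$housekeeping
  per_sample <- tbl |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(.reason = {
      genes_here <- unique(.data$gene)
      missing_hk <- setdiff(hk, genes_here)
      is_hk <- .data$gene %in% hk
      flagged <- is_hk & .data$status %in% c("ceiling_undetermined", "unreliable")
      if (length(missing_hk) > 0) {
        sprintf("housekeeping absent: %s", paste(missing_hk, collapse = ", "))
      } else if (sum(flagged) >= 2) {
        pts <- sprintf("%s rep%d %s", .data$gene[flagged],
                       .data$replicate[flagged], .data$status[flagged])
        sprintf("housekeeping quality: %s", paste(pts, collapse = "; "))
      } else {
        NA_character_
      }
    }, .groups = "drop")
  out <- tbl |>
    dplyr::left_join(per_sample, by = "sample_id") |>
    dplyr::mutate(sample_discarded = !is.na(.data$.reason),
                  discard_reason = .data$.reason) |>
    dplyr::select(-".reason")
  attr(out, "qc_params") <- attr(tbl, "qc_params")
  out
}

#' Summarise QC flags and sample discards
#'
#' @param tbl A QC-annotated table (after [discard_samples()]).
#' @return A list with `flag_counts` (tibble status -> n), `discards`
#'   (tibble `sample_id`, `discard_reason`), and counts `n_samples`,
#'   `n_discarded`.
#' @export
qc_summary <- function(tbl) {
  assert_columns(tbl, c("sample_id", "status"), what = "QC-annotated table")
  flag_counts <- dplyr::count(tbl, .data$status, name = "n")
  discards <- if ("sample_discarded" %in% names(tbl)) {
    tbl |>
      dplyr::filter(.data$sample_discarded) |>
      dplyr::distinct(.data$sample_id, .data$discard_reason)
  } else {
    tibble::tibble(sample_id = character(), discard_reason = character())
  }
  list(
    flag_counts = flag_counts,
    discards = discards,
    n_samples = dplyr::n_distinct(tbl$sample_id),
    n_discarded = nrow(discards)
  )
}
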