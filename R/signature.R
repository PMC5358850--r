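#' Define a gene-expression signature for qPCR risk scoring
#'
#' A signature definition bundles everything the pipeline needs to know about
#' the assay panel: the scored genes, the direction of regulation of each gene
#' in lymph-node-positive (LN+) tumors, the housekeeping genes used for sample
#' quality gating, the reference gene(s) used for delta-Ct normalization, and
#' the Ct ceiling that replaces doubly-undetermined replicate pairs.
#'
#' Directions use the convention `"up"` = higher expression (lower Ct) in LN+
#' tumors, `"down"` = lower expression (higher Ct) in LN+, and
#' `"unspecified"` for genes whose direction is unknown. Only genes with a
#' specified direction can enter the risk score.
#'
#' @param genes Character vector of gene symbols (non-empty, no duplicates,
#'   disjoint from `housekeeping`). Symbols are opaque, case-sensitive strings.
#' @param direction Named character vector mapping gene symbols to
#'   `"up"`, `"down"` or `"unspecified"`. Genes absent from the map default to
#'   `"unspecified"`.
#' @param housekeeping Character vector of housekeeping genes used for sample
#'   quality gating (default `c("ACTB", "HPRT")`).
#' @param reference_genes Genes whose average Ct is subtracted to form
#'   delta-Ct values (default `"ACTB"`; must be a subset of `housekeeping`
#'   or `genes`).
#' @param ct_ceiling Ct value (cycles) substituted when both replicates of a
#'   measurement are undetermined (default 35).
#' @param plate_control Optional sample label for an inter-plate control
#'   excluded from all statistics.
#' @param aliases Optional named character vector of alternate symbols
#'   (e.g. `c(FAM36A = "COX20")`), carried as metadata only.
#' @return An object of class `signature_definition`.
#' @export
#' @examples
#' sig <- signature_definition(
#'   genes = c("GA", "GB"),
#'   direction = c(GA = "up", GB = "down")
#' )
#' sig
signature_definition <- function(genes,
                                 direction = NULL,
                                 housekeeping = c("ACTB", "HPRT"),
                                 reference_genes = "ACTB",
                                 ct_ceiling = 35,
                                 plate_control = NULL,
                                 aliases = NULL) {
  genes <- as.character(genes)
  if (length(genes) == 0) abort("signature must contain at least one gene")
  if (anyDuplicated(genes)) {
    abort(sprintf("duplicated gene symbol(s): %s",
                  paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  overlap <- intersect(genes, housekeeping)
  if (length(overlap) > 0) {
    abort(sprintf("gene(s) in both signature and housekeeping set: %s",
                  paste(overlap, collapse = ", ")))
  }
  dir_full <- stats::setNames(rep("unspecified", length(genes)), genes)
  if (!is.null(direction)) {
    if (is.null(names(direction))) abort("`direction` must be a named vector")
    bad <- setdiff(names(direction), genes)
    if (length(bad) > 0) {
      abort(sprintf("direction given for unknown gene(s): %s",
                    paste(bad, collapse = ", ")))
    }
    ok <- c("up", "down", "unspecified")
    if (!all(direction %in% ok)) {
      abort("directions must be one of \"up\", \"down\", \"unspecified\"")
    }
    dir_full[names(direction)] <- direction
  }
  if (!is.numeric(ct_ceiling) || length(ct_ceiling) != 1 || ct_ceiling <= 0) {
    abort("`ct_ceiling` must be a single positive number")
  }
  structure(
    list(
      genes = genes,
      direction = dir_full,
      housekeeping = as.character(housekeeping),
      reference_genes = as.character(reference_genes),
      ct_ceiling = as.numeric(ct_ceiling),
      plate_control = plate_control,
      aliases = aliases
    ),
    class = "signature_definition"
  )
}

#' @export
print.signature_definition <- function(x, ...) {
  n_up <- sum(x$direction == "up")
  n_down <- sum(x$direction == "down")
  n_unspec <- sum(x$direction == "unspecified")
  cat(sprintf("<signature_definition> %d genes (%d up-in-LN+, %d down-in-LN+, %d unspecified)\n",
              length(x$genes), n_up, n_down, n_unspec))
  cat(sprintf("  housekeeping: %s | reference: %s | Ct ceiling: %g\n",
              paste(x$housekeeping, collapse = ", "),
              paste(x$reference_genes, collapse = ", "),
              x$ct_ceiling))
  invisible(x)
}

#' Genes of a signature with a given direction label
#'
#' @param sig A [signature_definition()].
#' @param direction One of `"up"`, `"down"`, `"unspecified"`.
#' @return Character vector of gene symbols.
#' @export
direction_genes <- function(sig, direction) {
  stopifnot(inherits(sig, "signature_definition"))
  names(sig$direction)[sig$direction == direction]
}

#' The 20-gene lymph-node metastasis signature
#'
#' Returns the 20-gene bladder-cancer lymph-node-metastasis qPCR panel with
#' housekeeping genes ACTB and HPRT, ACTB as delta-Ct reference, and a Ct
#' ceiling of 35. Eight genes have published directions of regulation in
#' LN+ disease (up: AVL9, PCMTD2, FAM36A, LIMCH1, RAB15; down: NCLN, MAP4K4,
#' MMP14); the remaining twelve are `"unspecified"` and must be supplied by
#' the user before they can enter a risk score.
#'
#' With `complete = TRUE` the twelve unspecified directions are filled with a
#' fixed synthetic convention (six up, six down) so that simulations and
#' worked examples can score all 20 genes. These completed directions are an
#' arbitrary, documented convention for synthetic data — they are not
#' published directions and must not be used to score real cohorts.
#'
#' @param complete Fill unspecified directions with the synthetic convention?
#' @return A [signature_definition()].
#' @export
#' @examples
#' default_signature()
#' direction_genes(default_signature(complete = TRUE), "down")
default_signature <- function(complete = FALSE) {
  genes <- c("TOX3", "SLC11A2", "FAM36A", "LIMCH1", "RAB15", "AVL9",
             "PCMTD2", "PTHLH", "DPP4", "PCDHGA10", "MT1E", "MAP4K4",
             "SLC16A1", "BST2", "MMP14", "IFI27", "NCLN", "HLA_G",
             "RRBP1", "ICAM1")
  direction <- c(
    AVL9 = "up", PCMTD2 = "up", FAM36A = "up", LIMCH1 = "up", RAB15 = "up",
    NCLN = "down", MAP4K4 = "down", MMP14 = "down"
  )
  if (complete) {
    # synthetic convention for the 12 genes without a published direction
    direction <- c(direction,
                   TOX3 = "up", SLC11A2 = "up", PTHLH = "up", DPP4 = "up",
                   PCDHGA10 = "up", MT1E = "up",
                   SLC16A1 = "down", BST2 = "down", IFI27 = "down",
                   HLA_G = "down", RRBP1 = "down", ICAM1 = "down")
  }
  signature_definition(
    genes = genes,
    direction = direction,
    housekeeping = c("ACTB", "HPRT"),
    reference_genes = "ACTB",
    ct_ceiling = 35,
    aliases = c(FAM36A = "COX20", HLA_G = "HLA G")
  )
}
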