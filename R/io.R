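#' Read a long-format Ct measurement table
#'
#' Reads a delimited text export of replicate-level qPCR Ct values. The file
#' must have a header with columns `sample_id`, `gene`, `replicate`,
#' `plate_id`, `ct` (an optional `well` column is carried through). The `ct`
#' column holds either a finite positive number of cycles or the instrument's
#' undetermined token (wells whose fluorescence never crossed threshold).
#'
#' @param path Path to a CSV or TSV file (delimiter guessed from the
#'   extension, override with `delim`).
#' @param undetermined Token marking undetermined wells, matched
#'   case-insensitively after trimming (default `"Undetermined"`).
#' @param delim Field delimiter; `NULL` uses `","` unless the extension is
#'   `.tsv`/`.txt`.
#' @return A tibble with columns `sample_id`, `gene`, `replicate`,
#'   `plate_id`, `ct` (numeric, `NA` for undetermined wells) and
#'   `undetermined` (logical). `ct` is `NA` if and only if `undetermined`
#'   is `TRUE`.
#' @export
read_ct_table <- function(path, undetermined = "Undetermined", delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), trim_ws = TRUE, progress = FALSE)
  assert_columns(raw, c("sample_id", "gene", "replicate", "plate_id", "ct"),
                 what = sprintf("Ct table '%s'", path))
  ct_chr <- trimws(raw$ct)
  is_und <- tolower(ct_chr) == tolower(undetermined)
  ct_num <- suppressWarnings(as.numeric(ct_chr))
  bad <- which(!is_und & (is.na(ct_num) | !is.finite(ct_num) | ct_num <= 0))
  if (length(bad) > 0) {
    abort(sprintf(
      "unparseable or non-positive ct value(s) that are not the undetermined token ('%s') at data row(s): %s",
      undetermined, paste(utils::head(bad, 10), collapse = ", ")))
  }
  ct_num[is_und] <- NA_real_
  out <- tibble::tibble(
    sample_id = raw$sample_id,
    gene = raw$gene,
    replicate = as.integer(raw$replicate),
    plate_id = raw$plate_id,
    ct = ct_num,
    undetermined = is_und
  )
  if ("well" %in% names(raw)) out$well <- raw$well
  validate_ct_table(out)
}

validate_ct_table <- function(tbl) {
  assert_columns(tbl, c("sample_id", "gene", "replicate", "plate_id",
                        "ct", "undetermined"), what = "Ct table")
  if (any(is.na(tbl$replicate)) || any(tbl$replicate < 1)) {
    abort("`replicate` must be an integer index >= 1")
  }
  if (any(is.na(tbl$ct) != tbl$undetermined)) {
    abort("`ct` must be NA exactly when `undetermined` is TRUE")
  }
  key <- paste(tbl$sample_id, tbl$gene, tbl$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- tbl[duplicated(key), , drop = FALSE][1, ]
    abort(sprintf(
      "duplicated (sample_id, gene, replicate) key: (%s, %s, %d)",
      d$sample_id, d$gene, d$replicate))
  }
  tbl
}

#' Write a Ct table back to delimited text
#'
#' Inverse of [read_ct_table()]: undetermined wells are written as the token,
#' everything else as plain numbers. Reading the file back yields an
#' identical table.
#'
#' @param tbl A Ct table as returned by [read_ct_table()].
#' @param path Output path (CSV).
#' @param undetermined Token to write for undetermined wells.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(tbl, path, undetermined = "Undetermined") {
  validate_ct_table(tbl)
  out <- tbl
  out$ct <- ifelse(out$undetermined, undetermined,
                   format(out$ct, digits = 15, trim = TRUE, scientific = FALSE))
  out$undetermined <- NULL
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a signature definition from a YAML or JSON config
#'
#' The config may contain keys `genes` (required), `direction` (map gene ->
#' up/down/unspecified), `housekeeping`, `reference_genes`, `ct_ceiling`,
#' `plate_control` and `aliases`; missing keys take the
#' [signature_definition()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param strict If `TRUE`, error when any gene's direction is unspecified
#'   (useful before scoring).
#' @return A [signature_definition()].
#' @export
read_signature_config <- function(path, strict = FALSE) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$genes)) abort(sprintf("config '%s' has no `genes` key", path))
  direction <- cfg$direction
  if (!is.null(direction)) direction <- unlist(direction)
  sig <- signature_definition(
    genes = unlist(cfg$genes),
    direction = direction,
    housekeeping = unlist(cfg$housekeeping) %||% c("ACTB", "HPRT"),
    reference_genes = unlist(cfg$reference_genes) %||% "ACTB",
    ct_ceiling = cfg$ct_ceiling %||% 35,
    plate_control = cfg$plate_control,
    aliases = unlist(cfg$aliases)
  )
  if (strict && any(sig$direction == "unspecified")) {
    abort(sprintf("strict mode: gene(s) with unspecified direction: %s",
                  paste(direction_genes(sig, "unspecified"), collapse = ", ")))
  }
  sig
}

#' Read a clinical annotation table
#'
#' @param path Delimited text with a header; columns `sample_id` and
#'   `ln_status` (values `POSITIVE`/`NEGATIVE`, empty or `NA` allowed for
#'   unknown nodal status) plus any number of covariate columns. Empty
#'   strings in covariate columns become the explicit level `"Unknown"`.
#' @param delim Field delimiter (guessed from the extension when `NULL`).
#' @return A tibble; `ln_status` is character with `NA` for unknown status.
#' @export
read_annotation <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  ann <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           trim_ws = TRUE, progress = FALSE)
  validate_annotation(ann)
}

#' Validate an in-memory clinical annotation table
#'
#' Checks the invariants of [read_annotation()] on a data frame built in
#' code: unique sample ids, `ln_status` in POSITIVE/NEGATIVE/NA, and
#' explicit `"Unknown"` levels for empty categorical covariates.
#'
#' @param ann A data frame with `sample_id`, `ln_status` and optional
#'   covariate columns.
#' @return The validated tibble.
#' @export
validate_annotation <- function(ann) {
  assert_columns(ann, c("sample_id", "ln_status"), what = "annotation table")
  if (anyDuplicated(ann$sample_id)) abort("duplicated sample_id in annotation")
  st <- ann$ln_status
  st[!is.na(st) & st == ""] <- NA
  bad <- !is.na(st) & !st %in% c("POSITIVE", "NEGATIVE")
  if (any(bad)) {
    abort(sprintf("ln_status must be POSITIVE/NEGATIVE/NA; offending value(s): %s",
                  paste(unique(st[bad]), collapse = ", ")))
  }
  ann$ln_status <- st
  # explicit Unknown level for categorical covariates
  covars <- setdiff(names(ann), c("sample_id", "ln_status"))
  for (v in covars) {
    if (is.character(ann[[v]])) {
      x <- ann[[v]]
      x[is.na(x) | x == ""] <- "Unknown"
      ann[[v]] <- x
    }
  }
  ann
}

#' Read a genes-by-samples expression matrix with group labels
#'
#' @param values_path Delimited text, genes as rows: first column `gene`,
#'   remaining columns one per sample.
#' @param groups_path Delimited text with columns `sample_id`, `group`.
#' @param unit Free-text unit tag carried as an attribute.
#' @param delim Field delimiter (guessed when `NULL`).
#' @return A list with elements `expression` (long tibble: `gene`,
#'   `sample_id`, `expression`) and `groups` (tibble `sample_id`, `group`).
#' @export
read_expression_matrix <- function(values_path, groups_path,
                                   unit = "expression", delim = NULL) {
  guess <- function(p) {
    if (grepl("\\.(tsv|txt)$", p, ignore.case = TRUE)) "\t" else ","
  }
  vals <- readr::read_delim(values_path, delim = delim %||% guess(values_path),
                            show_col_types = FALSE, progress = FALSE)
  assert_columns(vals, "gene", what = "expression matrix")
  if (anyDuplicated(vals$gene)) abort("duplicated gene in expression matrix")
  long <- tidyr::pivot_longer(vals, -"gene", names_to = "sample_id",
                              values_to = "expression")
  groups <- readr::read_delim(groups_path, delim = delim %||% guess(groups_path),
                              show_col_types = FALSE, progress = FALSE)
  assert_columns(groups, c("sample_id", "group"), what = "group table")
  if (anyDuplicated(groups$sample_id)) abort("duplicated sample_id in group table")
  list(expression = long, groups = groups, unit = unit)
}
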