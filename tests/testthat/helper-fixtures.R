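# Shared fixture builders for the test suite. Everything is constructed in
# code except qc_fixture.csv, a hand-written 6-sample plate export whose
# expected flags, discards and delta-Ct values were derived by hand (see
# fixture_key()).

tiny_signature <- function() {
  signature_definition(
    genes = c("GA", "GB"),
    direction = c(GA = "up", GB = "down"),
    housekeeping = c("ACTB", "HPRT"),
    reference_genes = "ACTB",
    ct_ceiling = 35
  )
}

# build a Ct table from a compact spec: list of c(sample, gene, rep, ct)
# with ct = NA meaning undetermined
make_ct <- function(rows, plate = "PL1") {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(sample_id = r[[1]], gene = r[[2]],
               replicate = as.integer(r[[3]]),
               plate_id = plate,
               ct = suppressWarnings(as.numeric(r[[4]])),
               stringsAsFactors = FALSE)
  }))
  df$undetermined <- is.na(df$ct)
  tibble::as_tibble(df)[, c("sample_id", "gene", "replicate", "plate_id",
                            "ct", "undetermined")]
}

# a clean two-replicate table for n samples with per-gene Ct maps
make_cohort_ct <- function(ct_by_gene, samples, plate = "PL1") {
  rows <- list()
  for (s in samples) for (g in names(ct_by_gene)) for (r in 1:2) {
    rows[[length(rows) + 1]] <- list(s, g, r, ct_by_gene[[g]])
  }
  make_ct(rows, plate = plate)
}

fixture_path <- function() test_path("qc_fixture.csv")

# hand-derived answer key for qc_fixture.csv:
#   GA usable values: 11 x 24 plus one 30 -> mean 24.5, sd sqrt(3);
#     1.96-sd interval [21.105, 27.895] -> S6 rep1 (30) unreliable
#   HPRT: 11 x 22 plus one 28 -> interval [19.105, 25.895] -> S5 rep1 (28)
#     unreliable
#   GB: S3 pair undetermined -> both 35 ceiling_undetermined; remaining 10
#     values all 26 (zero spread) -> ok
#   ACTB: S4 pair undetermined -> ceiling; remaining 10 x 20 -> ok
#   S2 GA rep2 imputed from rep1 (24)
#   discard: S4 only (two ceiling housekeeping points)
#   delta-Ct (ref ACTB = 20): GA = 4 everywhere (S6 collapses to the
#     surviving 24), GB = 6 except S3 = 35 - 20 = 15, HPRT = 2
fixture_key <- function() {
  flags <- tibble::tribble(
    ~sample_id, ~gene, ~replicate, ~status,
    "S2", "GA", 2L, "imputed_from_replicate",
    "S3", "GB", 1L, "ceiling_undetermined",
    "S3", "GB", 2L, "ceiling_undetermined",
    "S4", "ACTB", 1L, "ceiling_undetermined",
    "S4", "ACTB", 2L, "ceiling_undetermined",
    "S5", "HPRT", 1L, "unreliable",
    "S6", "GA", 1L, "unreliable"
  )
  dct <- tibble::tribble(
    ~sample_id, ~gene, ~delta_ct, ~n_replicates_used,
    "S1", "GA", 4, 2L, "S1", "GB", 6, 2L, "S1", "HPRT", 2, 2L,
    "S2", "GA", 4, 2L, "S2", "GB", 6, 2L, "S2", "HPRT", 2, 2L,
    "S3", "GA", 4, 2L, "S3", "GB", 15, 2L, "S3", "HPRT", 2, 2L,
    "S5", "GA", 4, 2L, "S5", "GB", 6, 2L, "S5", "HPRT", 2, 1L,
    "S6", "GA", 4, 1L, "S6", "GB", 6, 2L, "S6", "HPRT", 2, 2L
  )
  list(flags = flags, discarded = "S4", dct = dct)
}

run_qc <- function(ct, sig = tiny_signature(), ...) {
  ct |>
    reconcile_replicates(sig) |>
    flag_unreliable(...) |>
    discard_samples(sig)
}

# annotation reconstructed from the printed cohort counts: 91 LN- / 48 LN+,
# lymphovascular invasion 12 yes / 14 no / 65 unknown vs 18 / 2 / 28,
# gender 74 / 17 male/female vs 37 / 11
table1_annotation <- function() {
  mk <- function(status, lvi_y, lvi_n, lvi_u, male, female, prefix) {
    n <- lvi_y + lvi_n + lvi_u
    tibble::tibble(
      sample_id = sprintf("%s%03d", prefix, seq_len(n)),
      ln_status = status,
      lvi = c(rep("Yes", lvi_y), rep("No", lvi_n), rep("Unknown", lvi_u)),
      gender = c(rep("Male", male), rep("Female", female)),
      age = NA_real_)
  }
  neg <- mk("NEGATIVE", 12, 14, 65, 74, 17, "N")
  pos <- mk("POSITIVE", 18, 2, 28, 37, 11, "P")
  set.seed(1)
  out <- dplyr::bind_rows(neg, pos)
  out$age <- round(rnorm(nrow(out), 64, 9))
  out
}

# brute-force AUC by pair counting with half credit for ties
pair_auc <- function(pos, neg) {
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# independent exact Mann-Whitney oracle: enumerate every group assignment,
# computing U by direct pair counting
enum_mwu_p <- function(x, y) {
  n1 <- length(x)
  comb <- c(x, y)
  mu <- n1 * length(y) / 2
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  idx <- utils::combn(length(comb), n1)
  us <- apply(idx, 2, function(ii) u_of(comb[ii], comb[-ii]))
  mean(abs(us - mu) >= abs(u_of(x, y) - mu) - 1e-9)
}
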