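test_that("replicate reconciliation follows the undetermined rules", {
  sig <- tiny_signature()
  ct <- make_ct(list(
    list("S1", "GA", 1, 24.1), list("S1", "GA", 2, NA),    # single undetermined
    list("S1", "GB", 1, NA), list("S1", "GB", 2, NA),      # double undetermined
    list("S1", "ACTB", 1, 20.0), list("S1", "ACTB", 2, 20.2)  # clean pair
  ))
  rec <- reconcile_replicates(ct, sig)
  ga <- rec[rec$gene == "GA", ]
  expect_equal(ga$ct, c(24.1, 24.1))
  expect_equal(ga$status, c("ok", "imputed_from_replicate"))
  gb <- rec[rec$gene == "GB", ]
  expect_equal(gb$ct, c(35, 35))
  expect_equal(gb$status, rep("ceiling_undetermined", 2))
  actb <- rec[rec$gene == "ACTB", ]
  expect_equal(actb$ct, c(20.0, 20.2))
  expect_equal(actb$status, c("ok", "ok"))
  expect_false(anyNA(rec$ct))

  # >2 replicates: error in strict mode, pooled rule otherwise
  ct3 <- make_ct(list(list("S1", "GA", 1, 24), list("S1", "GA", 2, 25),
                      list("S1", "GA", 3, NA)))
  expect_error(reconcile_replicates(ct3, sig), "more than 2 replicates")
  rec3 <- reconcile_replicates(ct3, sig, strict = FALSE)
  expect_equal(rec3$ct[3], 24.5)
})

test_that("reliability flagging uses the per-transcript interval", {
  sig <- tiny_signature()
  # GA: 11 values at 24 and one at 30 -> mean 24.5, sd sqrt(3),
  # 1.96-interval [21.105, 27.895]
  rows <- list()
  for (s in sprintf("S%d", 1:6)) for (r in 1:2) {
    rows[[length(rows) + 1]] <- list(s, "GA", r, 24)
    rows[[length(rows) + 1]] <- list(s, "ACTB", r, 20)
    rows[[length(rows) + 1]] <- list(s, "HPRT", r, 22)
  }
  ct <- make_ct(rows)
  ct$ct[ct$sample_id == "S6" & ct$gene == "GA" & ct$replicate == 1] <- 30
  flagged <- reconcile_replicates(ct, sig) |> flag_unreliable()
  ga <- flagged[flagged$gene == "GA", ]
  expect_equal(sum(ga$status == "unreliable"), 1)
  expect_equal(ga$sample_id[ga$status == "unreliable"], "S6")
  # values inside the interval stay ok
  expect_true(all(ga$status[ga$ct == 24] == "ok"))
  # zero-spread genes: equal values pass
  expect_true(all(flagged$status[flagged$gene == "ACTB"] == "ok"))

  # ceiling values are excluded from the interval and never reflagged
  ct2 <- ct
  ct2$ct[ct2$sample_id == "S1" & ct2$gene == "GA"] <- NA
  ct2$undetermined <- is.na(ct2$ct)
  f2 <- reconcile_replicates(ct2, sig) |> flag_unreliable()
  s1 <- f2[f2$sample_id == "S1" & f2$gene == "GA", ]
  expect_equal(s1$status, rep("ceiling_undetermined", 2))
  expect_equal(s1$ct, c(35, 35))

  # fewer than 3 usable values: skipped with a warning
  small <- make_ct(list(list("S1", "GA", 1, 24), list("S1", "GA", 2, 90)))
  expect_warning(reconcile_replicates(small, sig) |> flag_unreliable(),
                 "fewer than 3")
})

test_that("percentile mode flags outside the central empirical interval", {
  sig <- tiny_signature()
  rows <- list()
  for (i in 1:50) rows[[i]] <- list(sprintf("S%02d", i), "GA", 1, i)
  ct <- make_ct(rows)
  f <- reconcile_replicates(ct, sig) |>
    flag_unreliable(method = "percentile", coverage = 0.9)
  # values below the 5th / above the 95th percentile are flagged
  expect_true(all(f$status[f$ct <= 3] == "unreliable"))
  expect_true(all(f$status[f$ct >= 48] == "unreliable"))
  expect_true(all(f$status[f$ct > 5 & f$ct < 47] == "ok"))
})

test_that("sample discard counts pooled housekeeping data points", {
  sig <- tiny_signature()
  base <- function(s) list(
    list(s, "ACTB", 1, 20), list(s, "ACTB", 2, 20),
    list(s, "HPRT", 1, 22), list(s, "HPRT", 2, 22),
    list(s, "GA", 1, 24), list(s, "GA", 2, 24))
  samples <- sprintf("S%02d", 1:12)
  ct <- make_ct(do.call(c, lapply(samples, base)))
  # S01: one ACTB + one HPRT replicate far outside the interval -> 2 points
  ct$ct[ct$sample_id == "S01" & ct$replicate == 1 &
          ct$gene %in% c("ACTB", "HPRT")] <- 60
  # S02: exactly one flagged housekeeping point
  ct$ct[ct$sample_id == "S02" & ct$gene == "HPRT" & ct$replicate == 1] <- 60
  # S03: both ACTB replicates undetermined -> 2 ceiling points
  ct$ct[ct$sample_id == "S03" & ct$gene == "ACTB"] <- NA
  ct$undetermined <- is.na(ct$ct)
  qc <- run_qc(ct)
  disc <- qc_summary(qc)$discards
  expect_setequal(disc$sample_id, c("S01", "S03"))
  r1 <- disc$discard_reason[disc$sample_id == "S01"]
  expect_match(r1, "ACTB rep1 unreliable")
  expect_match(r1, "HPRT rep1 unreliable")
  expect_match(disc$discard_reason[disc$sample_id == "S03"],
               "ACTB rep1 ceiling_undetermined")
  # exactly one flagged point, or none -> retained
  expect_false(any(c("S02", "S04") %in% disc$sample_id))

  # housekeeping gene absent entirely -> discarded with that reason
  ct2 <- make_ct(c(base("S1"), base("S2")[-(3:4)]))
  qc2 <- suppressWarnings(run_qc(ct2))
  d2 <- qc_summary(qc2)$discards
  expect_equal(d2$sample_id, "S2")
  expect_match(d2$discard_reason, "housekeeping absent: HPRT")
})

test_that("delta-Ct arithmetic, collapse and missingness behave as stated", {
  sig <- tiny_signature()
  ct <- make_ct(list(
    list("S1", "ACTB", 1, 20), list("S1", "ACTB", 2, 20),
    list("S1", "HPRT", 1, 22), list("S1", "HPRT", 2, 22),
    list("S1", "GA", 1, 26), list("S1", "GA", 2, 26),
    list("S2", "ACTB", 1, 19), list("S2", "ACTB", 2, 21),
    list("S2", "HPRT", 1, 22), list("S2", "HPRT", 2, 22),
    list("S2", "GA", 1, 25), list("S2", "GA", 2, 27)
  ))
  dct <- run_qc(ct) |> compute_delta_ct(sig)
  expect_equal(dct$delta_ct[dct$sample_id == "S1" & dct$gene == "GA"], 6)
  # uneven replicates average first: (25+27)/2 - (19+21)/2 = 6
  expect_equal(dct$delta_ct[dct$sample_id == "S2" & dct$gene == "GA"], 6)
  # reference gene is not reported as a delta-Ct row
  expect_false("ACTB" %in% dct$gene)
  # keep_all mode returns per-replicate values
  ka <- run_qc(ct) |> compute_delta_ct(sig, collapse = "keep_all")
  expect_equal(sort(ka$delta_ct[ka$sample_id == "S2" & ka$gene == "GA"]),
               c(5, 7))

  # ceiling_policy = "missing" turns ceiling cells into NA
  ct2 <- make_ct(list(
    list("S1", "ACTB", 1, 20), list("S1", "ACTB", 2, 20),
    list("S1", "HPRT", 1, 22), list("S1", "HPRT", 2, 22),
    list("S1", "GA", 1, NA), list("S1", "GA", 2, NA)
  ))
  qc2 <- suppressWarnings(run_qc(ct2))
  dct2 <- compute_delta_ct(qc2, sig)
  expect_equal(dct2$delta_ct[dct2$gene == "GA"], 15)
  dct2m <- compute_delta_ct(qc2, sig, ceiling_policy = "missing")
  expect_true(is.na(dct2m$delta_ct[dct2m$gene == "GA"]))
})

test_that("a global Ct shift of a sample leaves its delta-Ct row unchanged", {
  sig <- tiny_signature()
  set.seed(11)
  rows <- list()
  for (s in sprintf("S%d", 1:5)) for (g in c("ACTB", "HPRT", "GA", "GB")) {
    for (r in 1:2) rows[[length(rows) + 1]] <- list(s, g, r, rnorm(1, 24, 2))
  }
  ct <- make_ct(rows)
  base <- reconcile_replicates(ct, sig) |> compute_delta_ct(sig)
  shifted_ct <- ct
  shifted_ct$ct[shifted_ct$sample_id == "S3"] <-
    shifted_ct$ct[shifted_ct$sample_id == "S3"] + 2
  shifted <- reconcile_replicates(shifted_ct, sig) |> compute_delta_ct(sig)
  expect_equal(shifted$delta_ct, base$delta_ct, tolerance = 1e-12)
})

test_that("the QC chain is idempotent and conserves measurements", {
  ct <- read_ct_table(fixture_path())
  once <- run_qc(ct)
  twice <- run_qc(once)
  expect_equal(twice$status, once$status)
  expect_equal(twice$ct, once$ct)
  expect_equal(twice$sample_discarded, once$sample_discarded)
  # flag conservation: every QC step preserves the row count
  expect_equal(nrow(once), nrow(ct))
})

test_that("the shipped 6-sample fixture reproduces its hand-derived key", {
  sig <- tiny_signature()
  key <- fixture_key()
  qc <- run_qc(read_ct_table(fixture_path()))

  flagged <- qc[qc$status != "ok",
                c("sample_id", "gene", "replicate", "status")]
  flagged <- flagged[order(flagged$sample_id, flagged$gene, flagged$replicate), ]
  expect_equal(tibble::as_tibble(flagged), key$flags, ignore_attr = TRUE)

  expect_equal(qc_summary(qc)$discards$sample_id, key$discarded)

  dct <- compute_delta_ct(qc, sig)
  got <- dct[, c("sample_id", "gene", "delta_ct", "n_replicates_used")]
  got <- got[order(got$sample_id, got$gene), ]
  want <- key$dct[order(key$dct$sample_id, key$dct$gene), ]
  expect_equal(tibble::as_tibble(got), tibble::as_tibble(want),
               tolerance = 1e-12, ignore_attr = TRUE)
})
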