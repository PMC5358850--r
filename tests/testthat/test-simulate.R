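test_that("simulation is seed-deterministic and validates its config", {
  cfg <- simulation_config(n_neg = 10, n_pos = 6)
  a <- simulate_ct_cohort(cfg, seed = 3)
  b <- simulate_ct_cohort(cfg, seed = 3)
  expect_identical(a$ct, b$ct)
  expect_identical(a$truth, b$truth)
  c <- simulate_ct_cohort(cfg, seed = 4)
  expect_false(identical(a$ct$ct, c$ct$ct))

  expect_error(simulation_config(n_neg = 0), "positive")
  expect_error(simulation_config(biological_sd = -1), "SDs")
  expect_error(simulation_config(effect = c(NOPE = 1)), "unknown gene")

  # two patients per plate by default
  per_plate <- table(table(unique(a$ct[c("sample_id", "plate_id")])$plate_id))
  expect_true(all(as.integer(names(per_plate)) <= 2))
})

test_that("dropout limits behave: no dropout below a hard midpoint", {
  cfg <- simulation_config(n_neg = 8, n_pos = 8, dropout_midpoint = 50,
                           dropout_steepness = 0)
  sim <- simulate_ct_cohort(cfg, seed = 1)
  expect_equal(sum(sim$ct$undetermined), 0)
  # and a midpoint below all Cts loses everything
  cfg2 <- simulation_config(n_neg = 3, n_pos = 3, dropout_midpoint = 5,
                            dropout_steepness = 0)
  sim2 <- simulate_ct_cohort(cfg2, seed = 1)
  expect_true(all(sim2$ct$undetermined))
})

test_that("a noiseless zero-effect cohort is fully degenerate", {
  cfg <- simulation_config(n_neg = 12, n_pos = 8, effect = 0,
                           biological_sd = 0, replicate_sd = 0,
                           dropout_midpoint = 100)
  sim <- simulate_ct_cohort(cfg, seed = 2)
  expect_equal(length(unique(sim$ct$ct)), 2)  # one signature Ct, one housekeeping Ct
  r <- simulate_and_evaluate(cfg, seed = 2)
  expect_equal(r$auc, 0.5)
  expect_true(r$degenerate)
})

test_that("per-gene substreams are stable when the panel grows", {
  sig2 <- signature_definition(c("GA", "GB"),
                               direction = c(GA = "up", GB = "down"))
  sig3 <- signature_definition(c("GA", "GB", "GC"),
                               direction = c(GA = "up", GB = "down", GC = "down"))
  cfg2 <- simulation_config(n_neg = 6, n_pos = 6, signature = sig2)
  cfg3 <- simulation_config(n_neg = 6, n_pos = 6, signature = sig3)
  a <- simulate_ct_cohort(cfg2, seed = 9)$truth
  b <- simulate_ct_cohort(cfg3, seed = 9)$truth
  for (g in c("GA", "GB", "ACTB", "HPRT")) {
    expect_identical(a$latent_ct[a$gene == g], b$latent_ct[b$gene == g])
  }
})

test_that("undetermined fraction is nondecreasing in baseline Ct", {
  sig <- signature_definition(sprintf("G%02d", 1:6),
                              direction = stats::setNames(
                                rep(c("up", "down"), 3), sprintf("G%02d", 1:6)))
  base <- stats::setNames(seq(24, 39, by = 3), sig$genes)
  cfg <- simulation_config(n_neg = 60, n_pos = 40, signature = sig,
                           baseline_ct = base)
  sim <- simulate_ct_cohort(cfg, seed = 5)
  frac <- sim$ct |>
    dplyr::filter(.data$gene %in% sig$genes) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(f = mean(.data$undetermined)) |>
    dplyr::arrange(.data$gene)
  expect_true(all(diff(frac$f) >= 0))
  expect_lt(frac$f[1], 0.01)
  expect_gt(frac$f[6], 0.9)
})

test_that("sample discard is independent of LN status under a neutral model", {
  cfg <- simulation_config(n_neg = 45, n_pos = 24)
  counts <- matrix(0, 2, 2,
                   dimnames = list(c("NEGATIVE", "POSITIVE"),
                                   c("kept", "discarded")))
  for (s in 1:60) {
    sim <- simulate_ct_cohort(cfg, seed = 4000 + s)
    qc <- run_qc(sim$ct, cfg$signature)
    d <- qc |> dplyr::distinct(.data$sample_id, .data$sample_discarded) |>
      dplyr::inner_join(sim$annotation, by = "sample_id")
    t0 <- table(factor(d$ln_status, c("NEGATIVE", "POSITIVE")),
                factor(d$sample_discarded, c(FALSE, TRUE)))
    counts <- counts + t0
  }
  expect_gt(suppressWarnings(stats::chisq.test(counts))$p.value, 0.01)
})

test_that("the closed-form AUC oracle matches hand calculations", {
  # zero effects -> 0.5
  expect_equal(expected_auc(simulation_config(effect = 0)), 0.5)
  # one up + one down gene, effect only on the down gene, per-gene
  # variance 1/2 -> score sd 1, mean shift 1 -> pnorm(1/sqrt(2))
  sig <- signature_definition(c("GD", "GU"),
                              direction = c(GD = "down", GU = "up"))
  cfg <- simulation_config(signature = sig, effect = c(GD = 1),
                           biological_sd = sqrt(0.5 - 0.25^2 / 2),
                           replicate_sd = 0.25)
  expect_equal(expected_auc(cfg), pnorm(1 / sqrt(2)), tolerance = 1e-12)
  expect_equal(round(expected_auc(cfg), 4), 0.7602)

  # doubling all SDs at fixed effects moves the value toward 0.5
  cfg2 <- simulation_config(signature = sig, effect = c(GD = 1),
                            biological_sd = 2 * sqrt(0.5 - 0.25^2 / 2),
                            replicate_sd = 0.5)
  expect_lt(expected_auc(cfg2), expected_auc(cfg))
  expect_gt(expected_auc(cfg2), 0.5)

  # degenerate: zero variance, zero effect
  cfg3 <- simulation_config(signature = sig, effect = 0,
                            biological_sd = 0, replicate_sd = 0)
  expect_equal(expected_auc(cfg3), 0.5)

  # trim-aware mode: no trimming happens with a huge multiplier, so the
  # two oracles agree there
  cfg4 <- simulation_config(effect = 1)
  expect_equal(expected_auc(cfg4, qc_multiplier = 50), expected_auc(cfg4),
               tolerance = 1e-6)
  # with the 1.96 rule the trim-aware value is smaller at intermediate effects
  cfg5 <- simulation_config(effect = 0.5)
  expect_lt(expected_auc(cfg5, qc_multiplier = 1.96), expected_auc(cfg5))
})

test_that("the closed-form oracle matches a direct score simulation", {
  # simulate the generative score model at large n (no QC, no dropout)
  cfg <- simulation_config(effect = 0.75, dropout_midpoint = 1000)
  sig <- cfg$signature
  down <- direction_genes(sig, "down")
  up <- direction_genes(sig, "up")
  set.seed(99)
  n <- 40000
  score_of <- function(shifted) {
    d <- sapply(down, function(g)
      cfg$baseline_ct[[g]] + (if (shifted) cfg$effect[[g]] else 0) +
        rnorm(n, 0, cfg$biological_sd) + rnorm(n, 0, cfg$replicate_sd / sqrt(2)))
    u <- sapply(up, function(g)
      cfg$baseline_ct[[g]] + (if (shifted) cfg$effect[[g]] else 0) +
        rnorm(n, 0, cfg$biological_sd) + rnorm(n, 0, cfg$replicate_sd / sqrt(2)))
    rowMeans(d) - rowMeans(u)
  }
  s_neg <- score_of(FALSE)
  s_pos <- score_of(TRUE)
  emp_auc <- mean(outer(s_pos[1:2000], s_neg[1:2000], ">"))
  expect_equal(emp_auc, expected_auc(cfg), tolerance = 0.02)
})

test_that("expression cohorts are seeded, shifted and sized as requested", {
  a <- simulate_expression_cohort(n_neg = 20, n_pos = 10, seed = 6)
  b <- simulate_expression_cohort(n_neg = 20, n_pos = 10, seed = 6)
  expect_identical(a$expression, b$expression)
  expect_equal(nrow(a$groups), 30)
  expect_equal(sum(a$groups$group == "POSITIVE"), 10)
  expect_true(all(a$expression$expression > 0))
  expect_error(simulate_expression_cohort(n_neg = -1), "positive")

  # a strongly shifted gene has the smallest p in most replicates
  hits <- sapply(1:10, function(s) {
    em <- simulate_expression_cohort(n_neg = 40, n_pos = 40,
                                     genes = sprintf("G%d", 1:5),
                                     effect = c(G3 = 2), seed = s)
    tab <- compare_cohort(em$expression, em$groups)
    tab$gene[which.min(tab$p_value)] == "G3"
  })
  expect_gt(mean(hits), 0.8)

  # zero shifts: p-values are roughly uniform across replicates
  ps <- unlist(lapply(1:30, function(s) {
    em <- simulate_expression_cohort(n_neg = 15, n_pos = 15,
                                     genes = sprintf("G%d", 1:4),
                                     effect = 0, seed = 100 + s)
    compare_cohort(em$expression, em$groups, exact = FALSE)$p_value
  }))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
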