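#' Configuration for a synthetic qPCR cohort
#'
#' Defines the generating model for a plate-structured qPCR validation
#' cohort: per gene, a patient's true Ct is
#' `baseline + group effect + biological noise`; each of the two technical
#' replicates adds independent replicate noise; each replicate well goes
#' undetermined with probability `plogis((ct - dropout_midpoint) /
#' dropout_steepness)`, reproducing the loss of high-Ct (low-expression)
#' wells. Housekeeping genes are generated with zero group effect. Patients
#' are assigned to plates two at a time.
#'
#' The group effect is a per-gene delta-delta-Ct shift applied in the LN+
#' group. Passing a single number applies a direction-consistent pattern:
#' `+effect` cycles for down-in-LN+ genes, `-effect` for up-in-LN+ genes
#' (lower Ct = higher expression), zero for unspecified and housekeeping
#' genes. A named vector gives full control (values are signed LN+ shifts).
#'
#' Default cohort sizes (91 LN-negative, 48 LN-positive), duplicate wells
#' and two patients per plate mirror the validation study design the
#' package models; the noise and dropout defaults (`biological_sd` 1.0,
#' `replicate_sd` 0.25 cycles, dropout midpoint 34, steepness 1.5) are
#' engineering choices documented in the methods vignette.
#'
#' @param n_neg,n_pos Group sizes (defaults 91 and 48).
#' @param signature A fully-directed [signature_definition()] (default
#'   `default_signature(complete = TRUE)`).
#' @param baseline_ct Baseline Ct for signature genes: a single number
#'   (default 26) or a named per-gene vector.
#' @param effect Scalar effect magnitude (cycles) applied
#'   direction-consistently, or a named signed per-gene vector.
#' @param biological_sd Patient-level (biological) SD in cycles (default 1).
#' @param replicate_sd Technical replicate SD in cycles (default 0.25).
#' @param housekeeping_ct Baseline Ct of the housekeeping genes (default 20).
#' @param dropout_midpoint Ct at which dropout probability is 50%
#'   (default 34).
#' @param dropout_steepness Logistic scale of the dropout curve in cycles
#'   (default 1.5); 0 gives a hard threshold at the midpoint.
#' @param patients_per_plate Patients per qPCR plate (default 2).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_neg = 91, n_pos = 48,
                              signature = default_signature(complete = TRUE),
                              baseline_ct = 26, effect = 0,
                              biological_sd = 1, replicate_sd = 0.25,
                              housekeeping_ct = 20,
                              dropout_midpoint = 34, dropout_steepness = 1.5,
                              patients_per_plate = 2) {
  stopifnot(inherits(signature, "signature_definition"))
  if (n_neg < 1 || n_pos < 1) abort("group sizes must be positive")
  if (biological_sd < 0 || replicate_sd < 0) abort("SDs must be >= 0")
  if (dropout_steepness < 0) abort("dropout_steepness must be >= 0")
  genes <- signature$genes
  base <- if (length(baseline_ct) == 1 && is.null(names(baseline_ct))) {
    stats::setNames(rep(as.numeric(baseline_ct), length(genes)), genes)
  } else {
    if (!all(genes %in% names(baseline_ct))) {
      abort("named `baseline_ct` must cover every signature gene")
    }
    as.numeric(baseline_ct[genes]) |> stats::setNames(genes)
  }
  eff <- if (length(effect) == 1 && is.null(names(effect))) {
    signed_effects(signature, effect)
  } else {
    e <- stats::setNames(rep(0, length(genes)), genes)
    bad <- setdiff(names(effect), genes)
    if (length(bad) > 0) {
      abort(sprintf("effect given for unknown gene(s): %s",
                    paste(bad, collapse = ", ")))
    }
    e[names(effect)] <- as.numeric(effect)
    e
  }
  structure(list(n_neg = n_neg, n_pos = n_pos, signature = signature,
                 baseline_ct = base, effect = eff,
                 biological_sd = biological_sd, replicate_sd = replicate_sd,
                 housekeeping_ct = housekeeping_ct,
                 dropout_midpoint = dropout_midpoint,
                 dropout_steepness = dropout_steepness,
                 patients_per_plate = patients_per_plate),
            class = "simulation_config")
}

#' Direction-consistent signed effect vector
#'
#' Maps a scalar delta-delta-Ct magnitude to per-gene signed LN+ shifts:
#' `+size` cycles for down-in-LN+ genes (lower expression, higher Ct in
#' LN+), `-size` for up-in-LN+ genes, 0 for unspecified genes.
#'
#' @param sig A [signature_definition()].
#' @param size Effect magnitude in cycles.
#' @return Named numeric vector over the signature genes.
#' @export
signed_effects <- function(sig, size) {
  e <- stats::setNames(rep(0, length(sig$genes)), sig$genes)
  e[direction_genes(sig, "down")] <- size
  e[direction_genes(sig, "up")] <- -size
  e
}

#' Simulate a plate-structured qPCR Ct cohort
#'
#' Draws a full replicate-level Ct table from a [simulation_config()]: one
#' gene at a time, from an independent seeded substream per gene (adding a
#' gene to the panel never perturbs the draws of the others), plus the
#' clinical annotation and the latent truth record.
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed; fully determines the output.
#' @return A list with elements `ct` (Ct table in [read_ct_table()] format),
#'   `annotation` (tibble `sample_id`, `ln_status`), `truth` (tibble
#'   `sample_id`, `gene`, `replicate`, `latent_ct`, `dropout_prob`,
#'   `undetermined`), `config` and `seed`.
#' @export
simulate_ct_cohort <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_neg + cfg$n_pos
  sample_id <- sprintf("P%04d", seq_len(n))
  ln_status <- c(rep("NEGATIVE", cfg$n_neg), rep("POSITIVE", cfg$n_pos))
  is_pos <- ln_status == "POSITIVE"

  # plate assignment: shuffled patient order, patients_per_plate per plate
  set.seed(derive_seed(seed, "plates"))
  ord <- sample.int(n)
  plate_of <- integer(n)
  plate_of[ord] <- ceiling(seq_len(n) / cfg$patients_per_plate)
  plate_id <- sprintf("PL%04d", plate_of)

  sig <- cfg$signature
  all_genes <- c(sig$genes, sig$housekeeping)
  base <- c(cfg$baseline_ct,
            stats::setNames(rep(cfg$housekeeping_ct, length(sig$housekeeping)),
                            sig$housekeeping))
  eff <- c(cfg$effect,
           stats::setNames(rep(0, length(sig$housekeeping)), sig$housekeeping))

  parts <- lapply(all_genes, function(g) {
    set.seed(derive_seed(seed, "gene", g))
    b <- stats::rnorm(n, 0, cfg$biological_sd)
    e1 <- stats::rnorm(n, 0, cfg$replicate_sd)
    e2 <- stats::rnorm(n, 0, cfg$replicate_sd)
    u1 <- stats::runif(n)
    u2 <- stats::runif(n)
    true_ct <- base[[g]] + eff[[g]] * is_pos + b
    lat <- c(true_ct + e1, true_ct + e2)
    pdrop <- dropout_prob(lat, cfg$dropout_midpoint, cfg$dropout_steepness)
    und <- c(u1, u2) < pdrop
    tibble::tibble(
      sample_id = rep(sample_id, 2),
      gene = g,
      replicate = rep(1:2, each = n),
      plate_id = rep(plate_id, 2),
      ct = ifelse(und, NA_real_, lat),
      undetermined = und,
      latent_ct = lat,
      dropout_prob = pdrop
    )
  })
  full <- dplyr::bind_rows(parts) |>
    dplyr::arrange(.data$sample_id, .data$gene, .data$replicate)
  ct <- dplyr::select(full, "sample_id", "gene", "replicate", "plate_id",
                      "ct", "undetermined")
  truth <- dplyr::select(full, "sample_id", "gene", "replicate",
                         "latent_ct", "dropout_prob", "undetermined")
  list(ct = ct,
       annotation = tibble::tibble(sample_id = sample_id,
                                   ln_status = ln_status),
       truth = truth, config = cfg, seed = seed)
}

dropout_prob <- function(ct, midpoint, steepness) {
  if (steepness == 0) {
    ifelse(ct > midpoint, 1, ifelse(ct < midpoint, 0, 0.5))
  } else {
    stats::plogis((ct - midpoint) / steepness)
  }
}

#' Simulate an external two-group expression cohort
#'
#' Generates a log-normal genes-by-samples expression matrix with optional
#' per-gene group shifts, emulating an RNA-seq-style external validation
#' cohort (default 239 node-negative + 126 node-positive = 365 samples).
#' Each gene draws from its own seeded substream.
#'
#' @param n_neg,n_pos Group sizes (defaults 239, 126).
#' @param genes Gene symbols (default: the 20 signature genes).
#' @param effect Scalar or named per-gene shift on the log2 scale applied in
#'   the positive group (default 0).
#' @param base_log2 Mean log2 expression (default 8).
#' @param sd_log2 SD of log2 expression (default 1.5).
#' @param seed Integer seed.
#' @return A list with `expression` (long tibble `gene`, `sample_id`,
#'   `expression`, positive linear-scale values), `groups` (tibble
#'   `sample_id`, `group` in POSITIVE/NEGATIVE) and `unit`.
#' @export
simulate_expression_cohort <- function(n_neg = 239, n_pos = 126,
                                       genes = default_signature()$genes,
                                       effect = 0, base_log2 = 8,
                                       sd_log2 = 1.5, seed = 1) {
  if (n_neg < 1 || n_pos < 1) abort("group sizes must be positive")
  n <- n_neg + n_pos
  sample_id <- sprintf("T%04d", seq_len(n))
  group <- c(rep("NEGATIVE", n_neg), rep("POSITIVE", n_pos))
  eff <- stats::setNames(rep(0, length(genes)), genes)
  if (length(effect) == 1 && is.null(names(effect))) {
    eff[] <- as.numeric(effect)
  } else {
    eff[names(effect)] <- as.numeric(effect)
  }
  expr <- purrr::map_dfr(genes, function(g) {
    set.seed(derive_seed(seed, "expr", g))
    z <- stats::rnorm(n, base_log2 + eff[[g]] * (group == "POSITIVE"), sd_log2)
    tibble::tibble(gene = g, sample_id = sample_id, expression = 2^z)
  })
  list(expression = expr,
       groups = tibble::tibble(sample_id = sample_id, group = group),
       unit = "synthetic linear expression (2^log2)")
}

#' Closed-form AUC implied by a simulation configuration
#'
#' Under the additive Gaussian noise model (and ignoring dropout and
#' reliability trimming), the risk score is a linear combination of
#' independent per-gene normals, so its two group distributions are normal
#' with a known mean difference and common variance. The reference-gene
#' contribution cancels exactly in the score (every delta-Ct of a sample
#' subtracts the same reference mean, and the score is a difference of two
#' delta-Ct means), and averaging two replicates halves the replicate
#' variance. The implied AUC is
#' `pnorm(dmu / (sigma * sqrt(2)))` with
#' `dmu = mean(effect[down]) - mean(effect[up])` and
#' `sigma^2 = (biological_sd^2 + replicate_sd^2 / 2) * (1/n_down + 1/n_up)`.
#'
#' With `qc_multiplier` set (e.g. 1.96, the pipeline default), the oracle
#' additionally models the per-transcript reliability rule applied by
#' [flag_unreliable()]: replicate values outside the pooled
#' `mean +/- multiplier * sd` interval of their gene are excluded before
#' collapsing, which truncates the tails of the per-gene distributions and
#' shrinks both the score's group separation and its variance. The
#' trim-aware group means and variances are obtained from truncated-normal
#' moments integrated over the patient-level distribution (dropout and
#' ceiling substitution, which are rare at the default baselines, are not
#' modelled). This is the appropriate oracle when comparing against the
#' full QC pipeline at intermediate effect sizes; the plain formula is
#' exact for the score before reliability trimming.
#'
#' @param cfg A [simulation_config()] whose signature has at least one gene
#'   in each direction.
#' @param qc_multiplier `NULL` (default) for the plain normal-model AUC, or
#'   the reliability-interval multiplier used by the pipeline (e.g. 1.96)
#'   for the trim-aware prediction.
#' @return The implied AUC (a number in `[0, 1]`; 0.5 when there is no
#'   effect, including the zero-variance zero-effect degenerate case).
#' @export
#' @examples
#' cfg <- simulation_config(effect = 0)
#' expected_auc(cfg)  # 0.5
expected_auc <- function(cfg, qc_multiplier = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  sig <- cfg$signature
  down <- direction_genes(sig, "down")
  up <- direction_genes(sig, "up")
  if (length(down) == 0 || length(up) == 0) {
    abort("signature must have genes in both directions")
  }
  if (!is.null(qc_multiplier)) {
    return(expected_auc_trimmed(cfg, down, up, qc_multiplier))
  }
  dmu <- mean(cfg$effect[down]) - mean(cfg$effect[up])
  s2_gene <- cfg$biological_sd^2 + cfg$replicate_sd^2 / 2
  s2_score <- s2_gene * (1 / length(down) + 1 / length(up))
  if (s2_score == 0) {
    if (dmu == 0) return(0.5)
    return(as.numeric(dmu > 0))
  }
  stats::pnorm(dmu / sqrt(2 * s2_score))
}

# Moments of a gene's collapsed cell value under the reliability rule.
# Replicates are kept when inside the pooled interval [m - ks, m + ks]; the
# cell is the mean of kept replicates (missing when none survive). Returns
# the probability the cell is present and the conditional mean/variance of
# the cell, for a group whose patient-level mean is `delta` (the gene's
# negative-group mean is the origin).
qc_cell_moments <- function(delta, e_g, p_pos, sb, sr, kappa) {
  m <- p_pos * e_g
  s <- sqrt(sb^2 + sr^2 + e_g^2 * p_pos * (1 - p_pos))
  L <- m - kappa * s
  U <- m + kappa * s
  if (sb == 0) {
    b <- delta
    db <- 1
    fb <- 1
  } else {
    b <- seq(delta - 7 * sb, delta + 7 * sb, length.out = 4001)
    db <- b[2] - b[1]
    fb <- stats::dnorm(b, delta, sb)
  }
  if (sr == 0) {
    q <- as.numeric(b >= L & b <= U)
    t1 <- 0 * b
    t2 <- 0 * b
  } else {
    a1 <- (L - b) / sr
    a2 <- (U - b) / sr
    q <- stats::pnorm(a2) - stats::pnorm(a1)
    tiny <- q < 1e-12
    qs <- pmax(q, 1e-12)
    t1 <- sr * (stats::dnorm(a1) - stats::dnorm(a2)) / qs
    e2 <- sr^2 * (1 + (a1 * stats::dnorm(a1) - a2 * stats::dnorm(a2)) / qs)
    t2 <- pmax(e2 - t1^2, 0)
    q[tiny] <- 0
    t1[tiny] <- 0
    t2[tiny] <- 0
  }
  pk1 <- 2 * q * (1 - q)
  pk2 <- q^2
  w <- pk1 + pk2
  varc <- ifelse(w > 0, t2 * (pk1 + pk2 / 2) / pmax(w, 1e-12), 0)
  Z <- sum(w * fb) * db
  if (Z <= 0) return(list(p_present = 0, mean = NA_real_, var = NA_real_))
  mu <- sum((b + t1) * w * fb) * db / Z
  m2 <- sum(((b + t1)^2 + varc) * w * fb) * db / Z
  list(p_present = Z, mean = mu, var = max(m2 - mu^2, 0))
}

# E[1/K | K >= 1] for K ~ Binomial(n, z): the variance inflation of a
# direction mean when some genes' cells are trimmed away.
inv_k_mean <- function(n, z) {
  k <- seq_len(n)
  pk <- stats::dbinom(k, n, z)
  if (sum(pk) <= 0) return(1 / n)
  sum(pk / k) / sum(pk)
}

expected_auc_trimmed <- function(cfg, down, up, kappa) {
  p_pos <- cfg$n_pos / (cfg$n_pos + cfg$n_neg)
  group_moments <- function(genes, pos) {
    mom <- lapply(genes, function(g) {
      e <- cfg$effect[[g]]
      qc_cell_moments(if (pos) e else 0, e, p_pos,
                      cfg$biological_sd, cfg$replicate_sd, kappa)
    })
    mu <- mean(vapply(mom, `[[`, numeric(1), "mean"))
    vbar <- mean(vapply(mom, `[[`, numeric(1), "var"))
    zbar <- mean(vapply(mom, `[[`, numeric(1), "p_present"))
    list(mu = mu, v = vbar * inv_k_mean(length(genes), zbar))
  }
  mu_v <- lapply(c(FALSE, TRUE), function(pos) {
    d <- group_moments(down, pos)
    u <- group_moments(up, pos)
    list(mu = d$mu - u$mu, v = d$v + u$v)
  })
  dmu <- mu_v[[2]]$mu - mu_v[[1]]$mu
  v <- mu_v[[1]]$v + mu_v[[2]]$v
  if (v == 0) {
    if (dmu == 0) return(0.5)
    return(as.numeric(dmu > 0))
  }
  stats::pnorm(dmu / sqrt(v))
}
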