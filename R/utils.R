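#' @importFrom rlang %||% abort warn .data
#' @importFrom stats pnorm qnorm sd quantile glm binomial coef predict
#'   cor hclust cutree as.dist fisher.test chisq.test rnorm runif plogis
#' @importFrom utils combn
NULL

# Round half away from zero (cohort-table percentages are reported this way;
# base round() goes to even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic per-key seed derivation so each gene (or other labelled
# stream) draws from its own substream: adding a gene to a simulation never
# perturbs the draws of the others. Kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% 2147483629
  v <- (as.numeric(seed) %% 2147483629) * 48271 + h
  as.integer(v %% 2147483629) + 1L
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
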