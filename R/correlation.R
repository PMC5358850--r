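#' Pearson correlation matrix with complete-linkage clustering on 1 - r
#'
#' Computes the genes-by-genes Pearson correlation matrix of delta-Ct values
#' over pairwise-complete samples and clusters the genes by complete-linkage
#' agglomeration on the distance `d = 1 - r`, reporting merge heights and
#' the cluster memberships at a cut height. The default cut height 0.34
#' groups genes correlated at `r >= 0.66`.
#'
#' Genes that are constant or have fewer than `min_pairs` pairwise-complete
#' observations with some partner produce undefined correlations; they are
#' kept in the matrix (as `NA`) but excluded from the clustering, with a
#' warning.
#'
#' @param dct Long delta-Ct tibble from [compute_delta_ct()] (at least 3
#'   samples).
#' @param cut_height Distance at which the dendrogram is cut for cluster
#'   membership (default 0.34).
#' @param min_pairs Minimum pairwise-complete observations per gene pair
#'   (default 3).
#' @return An object of class `nodesig_corr`: list with `r` (correlation
#'   matrix), `hclust` (the complete-linkage tree on 1 - r), `clusters`
#'   (named integer vector at `cut_height`), `cut_height`, `excluded`
#'   (genes left out of the clustering).
#' @export
correlation_cluster <- function(dct, cut_height = 0.34, min_pairs = 3) {
  m <- delta_ct_wide(dct)
  if (nrow(m) < 3) abort("at least 3 samples are required")
  suppressWarnings(r <- stats::cor(m, use = "pairwise.complete.obs",
                                   method = "pearson"))
  n_pair <- crossprod(!is.na(m))
  r[n_pair < min_pairs] <- NA
  diag(r) <- 1
  # drop genes with undefined pairs (constant, or too few shared samples),
  # greedily removing the worst offender until the submatrix is complete
  keep <- colnames(r)
  repeat {
    na_counts <- colSums(is.na(r[keep, keep, drop = FALSE]))
    if (all(na_counts == 0) || length(keep) <= 2) break
    keep <- setdiff(keep, names(which.max(na_counts)))
  }
  bad <- setdiff(colnames(r), keep)
  if (length(bad) > 0) {
    warn(sprintf("gene(s) with undefined correlations excluded from clustering: %s",
                 paste(bad, collapse = ", ")))
  }
  if (length(keep) < 2) abort("fewer than 2 genes with defined correlations")
  d <- stats::as.dist(1 - r[keep, keep])
  hc <- stats::hclust(d, method = "complete")
  clusters <- stats::cutree(hc, h = cut_height)
  structure(list(r = r, hclust = hc, clusters = clusters,
                 cut_height = cut_height, excluded = bad),
            class = "nodesig_corr")
}

#' @export
print.nodesig_corr <- function(x, ...) {
  nclust <- length(unique(x$clusters))
  multi <- sum(table(x$clusters) > 1)
  cat(sprintf("<nodesig_corr> %d genes, %d clusters at cut height %.2f (%d with >1 gene)\n",
              ncol(x$r), nclust, x$cut_height, multi))
  if (length(x$excluded) > 0) {
    cat(sprintf("  excluded from clustering: %s\n",
                paste(x$excluded, collapse = ", ")))
  }
  invisible(x)
}

#' @describeIn correlation_cluster Long tibble of pairwise correlations
#'   (`gene1 < gene2`) with cluster co-membership.
#' @param x A `nodesig_corr` object.
#' @param ... Unused.
#' @export
tidy.nodesig_corr <- function(x, ...) {
  genes <- colnames(x$r)
  pairs <- which(upper.tri(x$r), arr.ind = TRUE)
  g1 <- genes[pairs[, 1]]
  g2 <- genes[pairs[, 2]]
  same <- rep(NA, nrow(pairs))
  in_clust <- g1 %in% names(x$clusters) & g2 %in% names(x$clusters)
  same[in_clust] <- x$clusters[g1[in_clust]] == x$clusters[g2[in_clust]]
  tibble::tibble(gene1 = g1, gene2 = g2, r = x$r[pairs],
                 distance = 1 - x$r[pairs], same_cluster = same)
}

#' @describeIn correlation_cluster Correlation heatmap in dendrogram order.
#' @param object A `nodesig_corr` object.
#' @export
autoplot.nodesig_corr <- function(object, ...) {
  ord <- object$hclust$labels[object$hclust$order]
  ord <- c(ord, setdiff(colnames(object$r), ord))
  df <- as.data.frame(as.table(object$r[ord, ord]))
  names(df) <- c("gene1", "gene2", "r")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene1, y = .data$gene2,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "white", high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
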