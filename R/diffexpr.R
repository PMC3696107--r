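#' Signed fold change between two groups on the log2 scale
#'
#' Group means are taken on the log2 scale and back-transformed; the ratio
#' \code{r = 2^(mean_ref - mean_cmp)} is reported as \code{r} when
#' \code{r >= 1} and as \code{-1/r} otherwise, so magnitude is symmetric
#' about +/-1. Positive values mean higher expression in the reference
#' group (benignA in the subgroup contrast), negative values higher in the
#' comparison group.
#'
#' @param group_ref_log2,group_cmp_log2 Numeric vectors of log2
#'   intensities, each non-empty.
#' @return Signed fold change with \code{|FC| >= 1}.
#' @export
signed_fold_change <- function(group_ref_log2, group_cmp_log2) {
  if (length(group_ref_log2) < 1 || length(group_cmp_log2) < 1) {
    stop("both groups must be non-empty")
  }
  r <- 2^(mean(group_ref_log2) - mean(group_cmp_log2))
  if (r >= 1) r else -1 / r
}

#' Per-probe pooled-variance t-test
#'
#' Two-sided Student's t-test with pooled variance, computed row-wise
#' (vectorised) over a log2 expression matrix. Probes with zero pooled
#' variance take the degenerate convention p = 1 when the group means are
#' equal and p = 0 otherwise.
#'
#' @param matrix Numeric matrix, probes x samples, log2 scale, finite.
#' @param labels Vector of two group labels aligned to the columns.
#' @param ref_level Label treated as the reference group; default the first
#'   of the sorted unique labels.
#' @return Named numeric vector of p-values aligned to probe (row) order,
#'   with attributes \code{t} (statistics) and \code{df}.
#' @export
ttest_per_probe <- function(matrix, labels, ref_level = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("'matrix' must be a numeric matrix (probes x samples)")
  }
  if (any(!is.finite(matrix))) stop("expression values must be finite")
  labels <- as.character(labels)
  if (length(labels) != ncol(matrix)) {
    stop("'labels' length must match the number of samples")
  }
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop("exactly two groups required")
  if (is.null(ref_level)) ref_level <- lv[1]
  g1 <- labels == ref_level
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  x1 <- matrix[, g1, drop = FALSE]
  x2 <- matrix[, g2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- sp2 <= 0
  if (any(degen)) {
    p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
    tstat[degen] <- ifelse(m1[degen] == m2[degen], 0, Inf * sign(m1[degen] - m2[degen]))
  }
  names(p) <- rownames(matrix)
  attr(p, "t") <- tstat
  attr(p, "df") <- df
  p
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard step-up q-values: \code{q_(i) = min_(j >= i) p_(j) * m / j} over
#' the sorted p-values, mapped back to input order. Tied p-values share the
#' q of their last sorted occurrence, which the running minimum produces
#' automatically.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Vector of q-values in input order.
#' @export
bh_stepup <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  o <- order(p_values)
  q_sorted <- rev(cummin(rev(p_values[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  names(q) <- names(p_values)
  q
}

#' Select differentially expressed probes with the combined filter
#'
#' Applies the restrictive combined criterion used for the benignA-vs-
#' benignB contrast: absolute fold change of at least \code{fc_min},
#' p-value strictly below \code{p_max}, and Benjamini-Hochberg q-value at
#' most \code{fdr_max}. The FDR is computed over the full probe set before
#' any filtering. Records are returned sorted by fold change, descending
#' (positive FC = higher in the reference group first).
#'
#' @param matrix Probes x samples log2 matrix with probe rownames.
#' @param labels Two-group vector aligned to columns.
#' @param ref_level Reference group label (default first sorted label).
#' @param fc_min Minimum absolute fold change (inclusive), default 2.
#' @param p_max p-value threshold (strict), default 0.005.
#' @param fdr_max Maximum FDR q-value (inclusive), default 0.005.
#' @param annotations Optional data frame keyed by \code{probeset_id} with
#'   columns such as \code{gene_symbol}, \code{gene_title},
#'   \code{chromosomal_location}, merged into the output.
#' @return Object of class \code{c("de_table", "data.frame")} with columns
#'   probeset_id, gene_title, gene_symbol, chromosomal_location, p_value,
#'   fdr, fold_change.
#' @export
select_de <- function(matrix, labels, ref_level = NULL, fc_min = 2,
                      p_max = 0.005, fdr_max = 0.005, annotations = NULL) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (is.null(ref_level)) ref_level <- lv[1]
  p <- ttest_per_probe(matrix, labels, ref_level)
  q <- bh_stepup(p)
  g1 <- labels == ref_level
  fc <- vapply(seq_len(nrow(matrix)), function(i) {
    signed_fold_change(matrix[i, g1], matrix[i, !g1])
  }, numeric(1))
  keep <- abs(fc) >= fc_min & p < p_max & q <= fdr_max
  ids <- rownames(matrix)[keep]
  out <- data.frame(probeset_id = ids,
                    gene_title = rep(NA_character_, length(ids)),
                    gene_symbol = rep(NA_character_, length(ids)),
                    chromosomal_location = rep(NA_character_, length(ids)),
                    p_value = unname(p[keep]),
                    fdr = unname(q[keep]),
                    fold_change = fc[keep],
                    stringsAsFactors = FALSE)
  if (!is.null(annotations) && nrow(out) > 0) {
    idx <- match(out$probeset_id, annotations$probeset_id)
    for (col in intersect(c("gene_title", "gene_symbol", "chromosomal_location"),
                          names(annotations))) {
      out[[col]] <- annotations[[col]][idx]
    }
  }
  out <- out[order(-out$fold_change, out$probeset_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("de_table", "data.frame"),
            ref_level = ref_level, n_probes_tested = nrow(matrix),
            thresholds = c(fc_min = fc_min, p_max = p_max, fdr_max = fdr_max))
}

#' @export
print.de_table <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "%d differentially expressed probe sets (of %s tested; |FC| >= %g, p < %g, FDR <= %g)\n",
    nrow(x), attr(x, "n_probes_tested"), th["fc_min"], th["p_max"],
    th["fdr_max"]))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Unsupervised hierarchical clustering of samples
#'
#' Agglomerative clustering of samples over a set of (typically
#' differentially expressed) probes, with distance 1 - Pearson correlation
#' and average linkage — the prevailing convention for expression heat-map
#' dendrograms. A zero-variance sample has undefined correlations; these
#' are set to 0 with a warning. Ties in merge heights are broken
#' deterministically by the agglomeration order of \code{stats::hclust}
#' (lower index first).
#'
#' @param matrix Probes x samples log2 matrix (>= 2 samples, >= 2 probes),
#'   usually restricted to the probes selected by [select_de()].
#' @return List of class \code{"sample_clustering"} with \code{hclust} (the
#'   \code{stats::hclust} object), \code{leaf_order} (sample ids in
#'   dendrogram order) and \code{dist} (the distance object).
#' @export
hierarchical_cluster <- function(matrix) {
  if (ncol(matrix) < 2 || nrow(matrix) < 2) {
    stop("need at least 2 samples and 2 probes")
  }
  v <- apply(matrix, 2, stats::var)
  C <- suppressWarnings(stats::cor(matrix))
  if (any(v == 0)) {
    warning("zero-variance sample(s): ",
            paste(colnames(matrix)[v == 0], collapse = ", "),
            "; correlations set to 0")
  }
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  d <- stats::as.dist(1 - C)
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc,
                 leaf_order = hc$labels[hc$order],
                 dist = d),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat(sprintf("Average-linkage clustering of %d samples (1 - Pearson)\n",
              length(x$leaf_order)))
  cat("Leaf order:", paste(x$leaf_order, collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.sample_clustering <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "",
       main = "Sample clustering (1 - Pearson, average linkage)", ...)
  invisible(x)
}
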