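#' Exact two-tailed Fisher test for a 2x2 table
#'
#' Computes the two-sided exact p-value for a 2x2 contingency table by
#' enumerating the hypergeometric support with fixed margins and summing the
#' probabilities of all tables whose probability does not exceed that of the
#' observed table. This is the standard two-sided definition used for
#' subgroup-by-recurrence tables (rows = subgroup, columns = recurrence
#' yes/no).
#'
#' @param tab A 2x2 matrix of non-negative counts, or a numeric vector of
#'   length 4 read row-wise as \code{c(a, b, c, d)}.
#' @return The two-sided exact p-value, a number in (0, 1]. If any margin is
#'   zero only one table is possible and the p-value is 1.
#' @examples
#' fisher_exact_two_tailed(matrix(c(0, 9, 6, 5), 2, 2, byrow = TRUE))
#' @export
fisher_exact_two_tailed <- function(tab) {
  if (is.vector(tab) && length(tab) == 4L) {
    tab <- matrix(tab, 2L, 2L, byrow = TRUE)
  }
  if (!is.matrix(tab) || !all(dim(tab) == c(2L, 2L))) {
    stop("'tab' must be a 2x2 matrix or a length-4 vector")
  }
  if (any(tab < 0) || any(tab != round(tab)) || any(!is.finite(tab))) {
    stop("counts must be finite non-negative integers")
  }
  n <- sum(tab)
  if (n < 1) stop("table total must be >= 1")
  r1 <- sum(tab[1L, ])
  c1 <- sum(tab[, 1L])
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) {
    return(1)
  }
  # support of the (1,1) cell given fixed margins
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  dens <- stats::dhyper(support, c1, n - c1, r1)
  obs <- stats::dhyper(tab[1L, 1L], c1, n - c1, r1)
  # relative tolerance guards against ties broken by floating-point noise
  p <- sum(dens[dens <= obs * (1 + 1e-7)])
  min(1, p)
}

#' Summarize recurrence by molecular subgroup
#'
#' Computes per-group recurrence rates, builds the benignA-vs-benignB 2x2
#' table (rows = subgroup, columns = recurred yes/no) and attaches the exact
#' two-tailed Fisher p-value for the association of subgroup with
#' recurrence at follow-up.
#'
#' @param labels Character or factor vector of subgroup labels per patient
#'   (\code{"benignA"}, \code{"benignB"}, \code{"atypical"}).
#' @param outcomes Logical vector of recurrence outcomes, same length.
#' @return An object of class \code{"recurrence_summary"}: a list with
#'   \code{rates} (data frame with group, n, recurrences, rate),
#'   \code{table} (the benignA/benignB 2x2 matrix) and \code{p_value}.
#'   Groups with no patients get an \code{NA} rate and are flagged.
#' @export
recurrence_summary <- function(labels, outcomes) {
  if (length(labels) != length(outcomes)) {
    stop("'labels' and 'outcomes' must have the same length")
  }
  if (any(is.na(labels)) || any(is.na(outcomes))) {
    stop("every patient needs a label and an outcome")
  }
  labels <- as.character(labels)
  outcomes <- as.logical(outcomes)
  canonical <- c("benignA", "benignB", "atypical")
  groups <- c(canonical, setdiff(unique(labels), canonical))
  rates <- do.call(rbind, lapply(groups, function(g) {
    idx <- labels == g
    n <- sum(idx)
    rec <- sum(outcomes[idx])
    data.frame(group = g, n = n, recurrences = rec,
               rate = if (n > 0) rec / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  a <- sum(labels == "benignA" & outcomes)
  b <- sum(labels == "benignA" & !outcomes)
  cc <- sum(labels == "benignB" & outcomes)
  d <- sum(labels == "benignB" & !outcomes)
  tab <- matrix(c(a, b, cc, d), 2L, 2L, byrow = TRUE,
                dimnames = list(c("benignA", "benignB"),
                                c("recurred", "not_recurred")))
  p <- fisher_exact_two_tailed(tab)
  structure(list(rates = rates, table = tab, p_value = p),
            class = "recurrence_summary")
}

#' @export
print.recurrence_summary <- function(x, ...) {
  cat("Recurrence by subgroup\n")
  print(x$rates, row.names = FALSE)
  cat("\nbenignA vs benignB 2x2 table:\n")
  print(x$table)
  cat(sprintf("\nTwo-tailed exact Fisher p = %.3f\n", x$p_value))
  invisible(x)
}

#' Relative expression by the delta-delta-Ct method
#'
#' For each sample, the target gene's Ct is first normalized against the
#' reference gene of the same sample (delta-Ct), then against the mean
#' delta-Ct of a control group (delta-delta-Ct). Relative expression is
#' \code{2^(-ddCt)}, assuming 100\% amplification efficiency, so one cycle
#' fewer corresponds to a two-fold higher starting copy number.
#'
#' @param ct Data frame with columns \code{sample_id}, \code{group},
#'   \code{gene}, \code{ct} (threshold cycles, finite and positive).
#' @param target_gene Gene to quantify.
#' @param control_group Group whose mean delta-Ct defines the calibrator.
#' @param reference_gene Housekeeping gene used for per-sample
#'   normalization (default \code{"GAPDH"}).
#' @return An object of class \code{"ddct_result"}: list with
#'   \code{per_sample} (sample_id, group, dct, ddct, rel_expr) and
#'   \code{per_group} (group, n, mean, sd of relative expression). Samples
#'   lacking a reference Ct are excluded with a warning.
#' @export
ddct_fold_change <- function(ct, target_gene, control_group,
                             reference_gene = "GAPDH") {
  req <- c("sample_id", "group", "gene", "ct")
  if (!all(req %in% names(ct))) {
    stop("'ct' must have columns sample_id, group, gene, ct")
  }
  tgt <- ct[ct$gene == target_gene, , drop = FALSE]
  ref <- ct[ct$gene == reference_gene, , drop = FALSE]
  if (nrow(tgt) == 0) stop("target gene '", target_gene, "' not found")
  if (nrow(ref) == 0) stop("reference gene '", reference_gene, "' not found")
  miss <- setdiff(tgt$sample_id, ref$sample_id)
  if (length(miss) > 0) {
    warning("excluding samples without reference Ct: ",
            paste(miss, collapse = ", "))
    tgt <- tgt[!tgt$sample_id %in% miss, , drop = FALSE]
  }
  refct <- ref$ct[match(tgt$sample_id, ref$sample_id)]
  if (any(!is.finite(tgt$ct)) || any(!is.finite(refct))) {
    stop("Ct values must be finite")
  }
  dct <- tgt$ct - refct
  ctrl <- tgt$group == control_group
  if (!any(ctrl)) stop("control group '", control_group, "' has no samples")
  ddct <- dct - mean(dct[ctrl])
  rel <- 2^(-ddct)
  per_sample <- data.frame(sample_id = tgt$sample_id, group = tgt$group,
                           dct = dct, ddct = ddct, rel_expr = rel,
                           stringsAsFactors = FALSE)
  per_group <- do.call(rbind, lapply(unique(tgt$group), function(g) {
    v <- rel[tgt$group == g]
    data.frame(group = g, n = length(v), mean_rel_expr = mean(v),
               sd_rel_expr = if (length(v) > 1) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(target_gene = target_gene, reference_gene = reference_gene,
                 control_group = control_group, per_sample = per_sample,
                 per_group = per_group),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("ddCt relative expression of %s (reference %s, control %s)\n",
              x$target_gene, x$reference_gene, x$control_group))
  print(x$per_group, row.names = FALSE)
  invisible(x)
}

#' Exact two-sided Mann-Whitney rank-sum test
#'
#' Exact two-sided p-value from the full permutation distribution of the
#' rank-sum statistic, using mid-ranks for ties. All
#' \code{choose(nx + ny, nx)} assignments of the pooled ranks are
#' enumerated when the total sample size is at most \code{exact_max}; beyond
#' that a normal approximation with tie correction is used.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @param exact_max Largest total sample size for which the exact
#'   enumeration is used (default 20).
#' @return Two-sided p-value. Extremeness is measured by the absolute
#'   deviation of the rank sum of \code{x} from its null expectation, so
#'   the result is symmetric in \code{x} and \code{y}.
#' @export
mann_whitney_exact <- function(x, y, exact_max = 20L) {
  if (length(x) < 1 || length(y) < 1) {
    stop("both samples must be non-empty")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  r <- rank(c(x, y))  # mid-ranks for ties
  w_obs <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (n <= exact_max) {
    idx <- utils::combn(n, nx)
    w_all <- colSums(matrix(r[idx], nrow = nx))
    dev_obs <- abs(w_obs - mu)
    p <- mean(abs(w_all - mu) >= dev_obs - 1e-9)
  } else {
    # normal approximation with tie correction
    ties <- table(r)
    sigma2 <- nx * ny / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w_obs - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  min(1, p)
}
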