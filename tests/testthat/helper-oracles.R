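# Independent brute-force oracles used to check the analytic implementations.

# Two-sided Fisher p by direct enumeration over the (1,1) cell, with
# probabilities from binomial coefficients (not dhyper).
oracle_fisher2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  prob <- vapply(ks, function(k) {
    exp(lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1))
  }, numeric(1))
  obs <- prob[ks == a]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p via the U statistic counted from pairwise
# comparisons over every assignment of the pooled values.
oracle_mw <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_stat <- function(xx, yy) {
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_stat(x, y)
  mu <- nx * (n - nx) / 2
  idx <- utils::combn(n, nx)
  u_all <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Literal step-up: q_i = min over sorted positions j with p_(j) >= p_i of
# p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    js <- which(ps >= pi - 1e-15)
    min(1, min(ps[js] * m / js))
  }, numeric(1))
}

# Naive average-linkage agglomeration over a distance matrix; returns the
# sorted merge heights.
oracle_average_linkage_heights <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters <- c(clusters, list(merged))
  }
  sort(heights)
}

# TRUE when a 2-way partition reproduces the binary labels exactly
# (adjusted Rand index of 1 for two clusters).
partitions_agree <- function(cut, labels) {
  tab <- table(cut, labels)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
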