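# Seeded expression matrix with planted two-group effects, used by the
# differential-expression recovery checks.
planted_matrix <- function(seed, n_probes = 1000, n_planted = 50,
                           effect = 2, noise_sd = 0.25, n1 = 7, n2 = 8) {
  set.seed(seed)
  probe_ids <- sprintf("P%04d_at", seq_len(n_probes))
  base <- rnorm(n_probes, 7, 1)
  delta <- numeric(n_probes)
  delta[seq_len(n_planted)] <- sample(c(-1, 1), n_planted, TRUE) * effect
  labels <- c(rep("benignA", n1), rep("benignB", n2))
  m <- matrix(rnorm(n_probes * (n1 + n2), 0, noise_sd), n_probes) +
    base + outer(delta, as.numeric(labels == "benignB"))
  dimnames(m) <- list(probe_ids, sprintf("s%02d", seq_len(n1 + n2)))
  list(m = m, labels = labels, planted = probe_ids[seq_len(n_planted)])
}
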