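test_that("default configuration yields the 54-sample cohort structure", {
  b <- simulate_cohort(sim_config(seed = 2))
  expect_equal(nrow(b$samples), 54)
  expect_equal(sum(b$true_labels == "benignA"), 20)
  expect_equal(sum(b$true_labels == "benignB"), 20)
  expect_equal(sum(b$true_labels == "atypical"), 14)
  expect_equal(b$samples$grade, ifelse(b$true_labels == "atypical", "II", "I"))
  # all per-sample containers share the same identifiers
  ids <- b$samples$sample_id
  expect_equal(rownames(b$metabolite_truth), ids)
  expect_equal(names(b$spectra), ids)
  expect_equal(colnames(b$expression), ids)
  expect_setequal(unique(b$fish_counts$sample_id), ids)
  expect_true(all(b$planted_de_ids %in% rownames(b$expression)))
  # nuclei per sample/probe within the preferred 100-200 range
  tab <- table(b$fish_counts$sample_id, b$fish_counts$probe)
  expect_true(all(tab >= 100 & tab <= 200))
})

test_that("the same seed reproduces an identical bundle", {
  b1 <- simulate_cohort(sim_config(seed = 5, n_probes = 100,
                                   n_planted_de = 10))
  b2 <- simulate_cohort(sim_config(seed = 5, n_probes = 100,
                                   n_planted_de = 10))
  expect_identical(serialize(b1, NULL, xdr = TRUE),
                   serialize(b2, NULL, xdr = TRUE))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(n_benignA = 0), "n_benignA")
  expect_error(sim_config(n_planted_de = 300, n_probes = 100), "n_planted_de")
  expect_error(sim_config(recur_prob = c(benignA = 0, benignB = 1.4,
                                         atypical = 0.9)), "recur_prob")
  expect_error(sim_config(expr_noise_sd = -1), "expr_noise_sd")
  expect_error(sim_config(metab_sds = matrix(-1, 3, 4,
    dimnames = list(c("benignA", "benignB", "atypical"),
                    marker_metabolites()))), "metab_sds")
})

test_that("recurrence draws follow the configured group probabilities", {
  cfg <- sim_config(n_benignA = 500, n_benignB = 500, n_atypical = 500,
                    n_probes = 10, n_planted_de = 2, n_spectrum_points = 1024,
                    recur_prob = c(benignA = 0, benignB = 0.545,
                                   atypical = 0.9),
                    seed = 13)
  b <- simulate_cohort(cfg)
  for (g in c("benignA", "benignB", "atypical")) {
    p <- cfg$recur_prob[[g]]
    obs <- mean(b$samples$recurrence[b$true_labels == g])
    se <- sqrt(p * (1 - p) / 500)
    expect_lte(abs(obs - p), 3 * se + 1e-12)
  }
})

test_that("FISH abnormal-nuclei fractions track the configured rates", {
  cfg <- sim_config(seed = 14, n_probes = 10, n_planted_de = 2,
                    n_spectrum_points = 1024)
  b <- simulate_cohort(cfg)
  groups <- b$samples$group[match(b$fish_counts$sample_id,
                                  b$samples$sample_id)]
  for (g in c("benignA", "benignB", "atypical")) {
    for (pr in colnames(cfg$fish_alteration_fracs)) {
      sel <- groups == g & b$fish_counts$probe == pr
      n <- sum(sel)
      frac <- cfg$fish_alteration_fracs[g, pr]
      obs <- mean(b$fish_counts$test_signals[sel] < 2)
      se <- sqrt(frac * (1 - frac) / n)
      expect_lte(abs(obs - frac), 3 * se + 1e-12)
    }
  }
})

test_that("planted expression effects have the configured magnitude and sign", {
  cfg <- sim_config(seed = 15, n_probes = 300, n_planted_de = 30,
                    n_spectrum_points = 1024)
  b <- simulate_cohort(cfg)
  ga <- b$true_labels == "benignA"
  gb <- b$true_labels == "benignB"
  diffs <- rowMeans(b$expression[b$planted_de_ids, ga, drop = FALSE]) -
    rowMeans(b$expression[b$planted_de_ids, gb, drop = FALSE])
  # group-mean differences concentrate near +/- the planted effect
  expect_true(all(abs(abs(diffs) - cfg$de_log2_effect) < 0.5))
  null_diffs <- rowMeans(b$expression[-seq_len(30), ga]) -
    rowMeans(b$expression[-seq_len(30), gb])
  expect_true(all(abs(null_diffs) < 0.5))
})

test_that("Ct values mirror expression with a constant reference gene", {
  cfg <- sim_config(seed = 16, n_probes = 50, n_planted_de = 5,
                    n_spectrum_points = 1024, ct_noise_sd = 0.05)
  b <- simulate_cohort(cfg)
  ref <- b$ct_table[b$ct_table$gene == "GAPDH", ]
  expect_true(all(ref$ct == 20))
  g1 <- b$ct_table[b$ct_table$gene == b$planted_de_ids[1], ]
  pred <- cfg$ct_intercept - b$expression[b$planted_de_ids[1], g1$sample_id]
  expect_lt(max(abs(g1$ct - pred)), 4 * cfg$ct_noise_sd + 0.2)
})

test_that("synthetic spectra conserve area and follow NMR conventions", {
  sp <- synth_spectrum(c(choline = 100))
  expect_true(all(diff(sp$ppm) < 0))  # decreasing ppm axis
  integral <- sum(-diff(sp$ppm) * (head(sp$intensity, -1) +
                                     tail(sp$intensity, -1)) / 2)
  expect_lt(abs(integral - 100) / 100, 1e-3)

  # disjoint windows, symmetric about two well-separated single Lorentzians,
  # integrate in the configured 3:7 ratio (equal capture fractions cancel)
  lib2 <- list(
    a = list(components = data.frame(center = 3.21, width = 0.004,
                                     weight = 1), window = c(3.01, 3.41)),
    b = list(components = data.frame(center = 0.90, width = 0.004,
                                     weight = 1), window = c(0.70, 1.10)))
  sp2 <- synth_spectrum(c(a = 30, b = 70), lib2)
  win_area <- function(sp, w) {
    sel <- sp$ppm >= w[1] & sp$ppm <= w[2]
    x <- rev(sp$ppm[sel]); y <- rev(sp$intensity[sel])
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  }
  r <- win_area(sp2, lib2$a$window) / win_area(sp2, lib2$b$window)
  expect_equal(r, 3 / 7, tolerance = 1e-3)

  # reproducible under a fixed seed even with noise
  set.seed(17); a <- synth_spectrum(c(choline = 10), noise_sd = 1)
  set.seed(17); b <- synth_spectrum(c(choline = 10), noise_sd = 1)
  expect_identical(a$intensity, b$intensity)

  expect_error(synth_spectrum(c(nonsense = 1)), "nonsense")
})
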