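make_profiles <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- marker_metabolites()
  rownames(m) <- paste0("s", seq_len(nrow(m)))
  m
}

test_that("atypical reference is the per-metabolite sample mean and SD", {
  m <- make_profiles(c(1, 1, 1, 1), c(2, 2, 2, 2), c(3, 3, 3, 3))
  ref <- build_reference(m)
  expect_equal(unname(ref$mean), rep(2, 4))
  expect_equal(unname(ref$sd), rep(1, 4))
  expect_equal(unname(ref$n), rep(3L, 4))

  # two identical samples collapse the interval to the mean
  ref2 <- build_reference(make_profiles(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(unname(ref2$sd), rep(0, 4))

  # a sample missing lactate is excluded from lactate statistics only
  m3 <- make_profiles(c(1, 1, 1, 1), c(2, NA, 2, 2), c(3, 3, 3, 3))
  ref3 <- build_reference(m3)
  expect_equal(unname(ref3$n["lactate"]), 2L)
  expect_equal(unname(ref3$n["choline"]), 3L)
  expect_equal(unname(ref3$mean["lactate"]), 2)

  expect_error(build_reference(make_profiles(c(1, 1, 1, 1))), "at least 2")
})

test_that("metabolic aggressiveness counts markers inside the 2-SD interval", {
  ref <- build_reference(make_profiles(c(1, 1, 1, 1), c(3, 3, 3, 3)))
  # means 2, SDs sqrt(2): interval [2 - 2*sqrt(2), 2 + 2*sqrt(2)]
  center <- setNames(rep(2, 4), marker_metabolites())
  agg <- metabolic_aggressiveness(center, ref)
  expect_equal(agg$n_markers_in_range, 4)
  expect_true(agg$aggressive)

  # three of four in range is enough
  three <- center
  three["choline"] <- 100
  agg3 <- metabolic_aggressiveness(three, ref)
  expect_equal(agg3$n_markers_in_range, 3)
  expect_true(agg3$aggressive)

  two <- three
  two["lactate"] <- 100
  expect_false(metabolic_aggressiveness(two, ref)$aggressive)

  # boundary exactly at mean - 2 SD is inclusive
  boundary <- setNames(rep(2 - 2 * sqrt(2), 4), marker_metabolites())
  expect_equal(metabolic_aggressiveness(boundary, ref)$n_markers_in_range, 4)

  # a missing marker counts as not-in-range and is flagged
  miss <- center
  miss["taurine"] <- NA
  aggm <- metabolic_aggressiveness(miss, ref)
  expect_equal(aggm$n_markers_in_range, 3)
  expect_equal(aggm$missing, "taurine")
})

ref_fixture <- function() {
  build_reference(make_profiles(c(2.0, 2.6, 1.6, 2.4), c(2.2, 2.8, 1.8, 2.6),
                                c(1.8, 2.4, 1.4, 2.2)))
}

karyo_22_only <- summarize_karyotype(
  list(structure(list(probe = "22", abnormal_fraction = 0.4,
                      cutoff_used = 0.2, status = "deletion"),
                 class = "alteration_call")), sample_id = "s")
karyo_1p_22 <- summarize_karyotype(
  list(structure(list(probe = "22", abnormal_fraction = 0.4,
                      cutoff_used = 0.2, status = "deletion"),
                 class = "alteration_call"),
       structure(list(probe = "1p", abnormal_fraction = 0.5,
                      cutoff_used = 0.2, status = "deletion"),
                 class = "alteration_call")), sample_id = "s")

test_that("classification applies grade precedence and the inclusive OR rule", {
  ref <- ref_fixture()
  far <- setNames(rep(0.1, 4), marker_metabolites())
  near <- ref$mean

  expect_equal(classify_sample("II")$label, "atypical")

  # grade I, isolated -22, metabolites far from atypical -> benignA
  expect_equal(classify_sample("I", karyo_22_only, far, ref)$label, "benignA")

  # chromosomal arm alone suffices
  expect_equal(classify_sample("I", karyo_1p_22, far, ref)$label, "benignB")

  # metabolic arm alone suffices (no karyotype data at all)
  lab <- classify_sample("I", NULL, near, ref)
  expect_equal(lab$label, "benignB")
  expect_false(lab$evidence$chromosomal)
  expect_true(lab$evidence$metabolic)

  expect_error(classify_sample("I"), "unclassifiable")
  expect_error(classify_sample("III", karyo_22_only), "grade")
})

test_that("improving evidence never demotes benignB to benignA", {
  ref <- ref_fixture()
  set.seed(61)
  for (rep in 1:40) {
    lv <- setNames(runif(4, 0, 4), marker_metabolites())
    base <- classify_sample("I", karyo_22_only, lv, ref)$label
    # adding an alteration beyond chromosome 22
    with_alt <- classify_sample("I", karyo_1p_22, lv, ref)$label
    if (base == "benignB") expect_equal(with_alt, "benignB")
    # moving one marker level to the reference mean
    m <- sample(marker_metabolites(), 1)
    lv2 <- lv
    lv2[m] <- ref$mean[[m]]
    moved <- classify_sample("I", karyo_22_only, lv2, ref)$label
    if (base == "benignB") expect_equal(moved, "benignB")
  }
})

test_that("every classifiable sample receives exactly one label", {
  cohort <- simulate_cohort(sim_config(seed = 8, n_benignA = 8, n_benignB = 8,
                                       n_atypical = 5, n_probes = 50,
                                       n_planted_de = 5))
  karyos <- lapply(split(cohort$fish_counts, cohort$fish_counts$sample_id),
                   function(d) {
                     calls <- lapply(split(d, d$probe), call_probe)
                     summarize_karyotype(calls, sample_id = d$sample_id[1])
                   })
  labels <- classify_cohort(cohort$samples, karyos, cohort$metabolite_truth)
  expect_equal(nrow(labels), nrow(cohort$samples))
  expect_true(all(labels$label %in% c("benignA", "benignB", "atypical")))
  expect_false(any(is.na(labels$label)))
})

test_that("classification recovers true labels on a well-separated cohort", {
  cohort <- simulate_cohort(sim_config(seed = 9))
  karyos <- lapply(split(cohort$fish_counts, cohort$fish_counts$sample_id),
                   function(d) {
                     calls <- lapply(split(d, d$probe), call_probe)
                     summarize_karyotype(calls, sample_id = d$sample_id[1])
                   })
  labels <- classify_cohort(cohort$samples, karyos, cohort$metabolite_truth)
  acc <- mean(labels$label == cohort$true_labels)
  expect_gte(acc, 0.95)
})
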