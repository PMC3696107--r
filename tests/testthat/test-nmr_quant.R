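single_peak_spectrum <- function(area = 100, center = 3.21, width = 0.004,
                                 noise_sd = 0, n_points = 4096) {
  synth_spectrum(setNames(area, "choline"),
                 peak_library = list(choline = list(
                   components = data.frame(center = center, width = width,
                                           weight = 1),
                   window = c(center - 0.05, center + 0.05))),
                 noise_sd = noise_sd, n_points = n_points)
}

test_that("a noiseless Lorentzian is recovered to numerical precision", {
  sp <- single_peak_spectrum(100)
  f <- fit_peak(sp, c(3.16, 3.26), 1)
  expect_true(f$accepted)
  expect_lt(abs(f$fitted_area - 100) / 100, 0.001)
  expect_lt(f$residual_error, 0.01)
})

test_that("areas survive noise at SNR 50 to within a few percent", {
  set.seed(91)
  height <- 100 / (pi * 0.004)  # peak height of the unit model times area
  errs <- replicate(20, {
    sp <- single_peak_spectrum(100, noise_sd = height / 50)
    f <- fit_peak(sp, c(3.16, 3.26), 1)
    abs(f$fitted_area - 100) / 100
  })
  expect_lt(median(errs), 0.05)
})

test_that("pure-noise windows fail the 10% residual rule", {
  set.seed(92)
  sp <- nmr_spectrum(seq(4.5, 0.2, length.out = 2048), rnorm(2048, 0, 1))
  f <- fit_peak(sp, c(2.0, 2.2), 1)
  expect_gte(f$residual_error, 0.10)
  expect_false(f$accepted)
})

test_that("window preconditions are enforced", {
  sp <- single_peak_spectrum()
  expect_error(fit_peak(sp, c(5.6, 5.8)), "outside")
  expect_error(fit_peak(sp, c(3.2100, 3.2105)), "16 points")
})

test_that("relative levels are peak area over total spectral area", {
  lib <- default_peak_library()
  # a single metabolite with no other signal self-normalizes to ~1
  sp1 <- synth_spectrum(c(choline = 80), lib)
  q1 <- quantify_metabolites(sp1, lib["choline"])
  expect_equal(unname(q1$levels["choline"]), 1, tolerance = 0.01)

  # two equal-area, well-separated peaks split the area evenly
  sp2 <- synth_spectrum(c(choline = 50, fatty_acids = 50), lib)
  q2 <- quantify_metabolites(sp2, lib[c("choline", "fatty_acids")])
  expect_equal(unname(q2$levels["choline"]), 0.5, tolerance = 0.01)
  expect_equal(unname(q2$levels["fatty_acids"]), 0.5, tolerance = 0.01)

  # 30:70 split recovered from disjoint windows
  sp3 <- synth_spectrum(c(choline = 30, fatty_acids = 70), lib)
  q3 <- quantify_metabolites(sp3, lib[c("choline", "fatty_acids")])
  ratio <- q3$levels[["choline"]] / q3$levels[["fatty_acids"]]
  expect_equal(ratio, 3 / 7, tolerance = 1e-3)
})

test_that("metabolites failing QC are flagged missing, not zero", {
  lib <- default_peak_library()
  set.seed(93)
  # taurine absent: its window holds only noise, so the fit is rejected
  sp <- synth_spectrum(c(choline = 50, lactate = 50), lib, noise_sd = 0.5)
  q <- quantify_metabolites(sp, lib[c("choline", "lactate", "taurine")])
  expect_true(is.na(q$levels["taurine"]))
  expect_false(q$accepted[["taurine"]])
  expect_true("taurine" %in% q$missing)
  expect_true(q$accepted[["choline"]])
})

test_that("overlapping windows and empty libraries are rejected", {
  sp <- single_peak_spectrum()
  lib <- list(a = list(components = data.frame(center = 3.2, width = 0.004,
                                               weight = 1),
                       window = c(3.1, 3.3)),
              b = list(components = data.frame(center = 3.25, width = 0.004,
                                               weight = 1),
                       window = c(3.25, 3.4)))
  expect_error(quantify_metabolites(sp, lib), "disjoint")
  expect_error(quantify_metabolites(sp, list()), "empty")
})

test_that("relative levels are invariant to intensity rescaling", {
  lib <- default_peak_library()
  sp <- synth_spectrum(c(choline = 40, lactate = 60), lib)
  q1 <- quantify_metabolites(sp, lib[c("choline", "lactate")])
  sp2 <- nmr_spectrum(sp$ppm, sp$intensity * 37.5, sp$sample_id)
  q2 <- quantify_metabolites(sp2, lib[c("choline", "lactate")])
  expect_equal(q1$levels, q2$levels, tolerance = 1e-6)
})

test_that("fitted areas never exceed the total integral for clean spectra", {
  lib <- default_peak_library()
  sp <- synth_spectrum(c(choline = 30, lactate = 20, taurine = 25,
                         fatty_acids = 25), lib)
  q <- quantify_metabolites(sp, lib[marker_metabolites()])
  # fitted areas are analytic (full-tail) areas while the denominator is the
  # on-axis integral, so the sum may exceed 1 by the off-axis tail mass
  expect_lte(sum(q$levels, na.rm = TRUE), 1 + 0.02)
})

test_that("residual error grows with additive noise on average", {
  height <- 100 / (pi * 0.004)
  mean_err <- vapply(c(0.002, 0.01, 0.05), function(rel) {
    set.seed(94)
    mean(replicate(10, {
      sp <- single_peak_spectrum(100, noise_sd = height * rel)
      fit_peak(sp, c(3.16, 3.26), 1)$residual_error
    }))
  }, numeric(1))
  expect_true(all(diff(mean_err) > 0))
})

test_that("cohort-level t-test matches the textbook pooled statistic", {
  p <- group_ttest(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3))
  expect_equal(as.numeric(p), 0.02131, tolerance = 1e-4)
  expect_equal(attr(p, "t"), -3.6742, tolerance = 1e-4)
  # label swap symmetry
  p2 <- group_ttest(c(1, 2, 3, 4, 5, 6), rep(c("B", "A"), each = 3))
  expect_equal(as.numeric(p2), as.numeric(p))
  # degenerate conventions
  expect_equal(as.numeric(group_ttest(rep(1, 6), rep(c("A", "B"), each = 3))), 1)
  expect_equal(as.numeric(group_ttest(c(1, 1, 1, 2, 2, 2),
                                      rep(c("A", "B"), each = 3))), 0)
  expect_error(group_ttest(c(1, 2, 3), c("A", "A", "B")), "at least 2")
})
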