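#' Configuration for a synthetic meningioma cohort
#'
#' Defines the statistical structure of a simulated cohort: group sizes
#' (default 20 benignA / 20 benignB / 14 atypical, a 54-sample cohort),
#' group-shifted marker-metabolite levels, per-probe FISH abnormal-nuclei
#' fractions, planted differential-expression effects, per-group four-year
#' recurrence probabilities (default 0, 6/11 and 0.9) and an RT-PCR Ct
#' model tied to expression.
#'
#' @param n_benignA,n_benignB,n_atypical Group sizes (counts > 0).
#' @param n_probes Number of expression probe sets.
#' @param n_planted_de Number of probes with a planted benignA-vs-benignB
#'   effect (<= n_probes).
#' @param de_log2_effect Magnitude of the planted log2 fold change.
#' @param expr_noise_sd Expression noise SD in log2 units.
#' @param recur_prob Named per-group recurrence probabilities in [0, 1].
#' @param metab_means,metab_sds Group x metabolite matrices (arbitrary
#'   units) for the four marker metabolites.
#' @param fish_alteration_fracs Group x probe matrix of the fraction of
#'   abnormal nuclei per FISH probe (1p, 14, 22).
#' @param nuclei_per_region Nuclei scored per tissue region (4 regions).
#' @param ct_noise_sd Ct noise in cycles.
#' @param ct_intercept Baseline cycles; Ct = intercept - log2 expression +
#'   noise, with a constant reference gene.
#' @param spectrum_noise_sd Gaussian noise SD of synthetic spectra
#'   (intensity units).
#' @param background_levels Named levels of constant non-marker resonances
#'   included in every spectrum so marker peaks do not dominate the total
#'   spectral area.
#' @param n_spectrum_points Points per synthetic spectrum (>= 1024).
#' @param seed Integer seed; all draws flow from this single generator.
#' @return Validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_benignA = 20L, n_benignB = 20L, n_atypical = 14L,
                       n_probes = 2000L, n_planted_de = 50L,
                       de_log2_effect = 2, expr_noise_sd = 0.25,
                       recur_prob = c(benignA = 0, benignB = 6 / 11,
                                      atypical = 0.9),
                       metab_means = NULL, metab_sds = NULL,
                       fish_alteration_fracs = NULL,
                       nuclei_per_region = 40L, ct_noise_sd = 0.15,
                       ct_intercept = 30, spectrum_noise_sd = 0.2,
                       background_levels = c(creatine = 15, glx = 12),
                       n_spectrum_points = 4096L, seed = 1L) {
  groups <- c("benignA", "benignB", "atypical")
  mets <- marker_metabolites()
  if (is.null(metab_means)) {
    metab_means <- rbind(benignA  = c(0.8, 1.0, 0.7, 1.2),
                         benignB  = c(2.0, 2.6, 1.6, 2.4),
                         atypical = c(2.0, 2.6, 1.6, 2.4))
    colnames(metab_means) <- mets
  }
  if (is.null(metab_sds)) {
    metab_sds <- rbind(benignA  = rep(0.10, 4),
                       benignB  = rep(0.15, 4),
                       atypical = rep(0.15, 4))
    colnames(metab_sds) <- mets
  }
  if (is.null(fish_alteration_fracs)) {
    fish_alteration_fracs <- rbind(benignA  = c(0.05, 0.05, 0.35),
                                   benignB  = c(0.45, 0.40, 0.50),
                                   atypical = c(0.60, 0.55, 0.55))
    colnames(fish_alteration_fracs) <- c("1p", "14", "22")
  }
  cfg <- list(n_benignA = as.integer(n_benignA),
              n_benignB = as.integer(n_benignB),
              n_atypical = as.integer(n_atypical),
              n_probes = as.integer(n_probes),
              n_planted_de = as.integer(n_planted_de),
              de_log2_effect = de_log2_effect,
              expr_noise_sd = expr_noise_sd,
              recur_prob = recur_prob,
              metab_means = metab_means, metab_sds = metab_sds,
              fish_alteration_fracs = fish_alteration_fracs,
              nuclei_per_region = as.integer(nuclei_per_region),
              ct_noise_sd = ct_noise_sd, ct_intercept = ct_intercept,
              spectrum_noise_sd = spectrum_noise_sd,
              background_levels = background_levels,
              n_spectrum_points = as.integer(n_spectrum_points),
              seed = as.integer(seed))
  validate_sim_config(cfg, groups, mets)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg, groups, mets) {
  cnt <- c("n_benignA", "n_benignB", "n_atypical", "n_probes",
           "n_planted_de", "nuclei_per_region", "n_spectrum_points")
  for (f in cnt) {
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("invalid configuration: '", f, "' must be a positive count")
    }
  }
  if (cfg$n_planted_de > cfg$n_probes) {
    stop("invalid configuration: 'n_planted_de' exceeds 'n_probes'")
  }
  if (!all(groups %in% names(cfg$recur_prob)) ||
      any(cfg$recur_prob < 0) || any(cfg$recur_prob > 1)) {
    stop("invalid configuration: 'recur_prob' needs per-group values in [0,1]")
  }
  for (f in c("metab_means", "metab_sds")) {
    m <- cfg[[f]]
    if (!all(groups %in% rownames(m)) || !all(mets %in% colnames(m))) {
      stop("invalid configuration: '", f,
           "' must be a group x marker-metabolite matrix")
    }
  }
  if (any(cfg$metab_sds < 0)) {
    stop("invalid configuration: 'metab_sds' must be >= 0")
  }
  ff <- cfg$fish_alteration_fracs
  if (!all(groups %in% rownames(ff)) || any(ff < 0) || any(ff > 1)) {
    stop("invalid configuration: 'fish_alteration_fracs' must be ",
         "group x probe fractions in [0,1]")
  }
  for (f in c("expr_noise_sd", "ct_noise_sd", "spectrum_noise_sd")) {
    if (cfg[[f]] < 0) stop("invalid configuration: '", f, "' must be >= 0")
  }
  invisible(cfg)
}

#' Simulate a complete synthetic meningioma cohort
#'
#' Draws, from a single seeded generator, every data stream the analysis
#' pipeline consumes: sample metadata with WHO grade and Bernoulli
#' recurrence outcomes, true marker-metabolite levels and synthetic 1D
#' spectra, per-nucleus FISH signal counts (deleted nuclei show the 1/2
#' pattern, normal nuclei 2/2), a log2 expression matrix with planted
#' differential effects between benignA and benignB (atypical samples get
#' 1.5x the planted shift, placing their signature beyond benignB), and an
#' RT-PCR Ct table in which target Ct equals a baseline minus the sample's
#' log2 expression plus noise while the reference gene is constant.
#'
#' @param config A \code{"sim_config"}.
#' @return Object of class \code{"cohort_bundle"}: list with
#'   \code{samples}, \code{metabolite_truth}, \code{spectra},
#'   \code{fish_counts}, \code{expression}, \code{planted_de_ids},
#'   \code{ct_table}, \code{true_labels} and \code{config}. Identical
#'   configs (same seed) yield identical bundles.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  groups <- c(rep("benignA", config$n_benignA),
              rep("benignB", config$n_benignB),
              rep("atypical", config$n_atypical))
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  grade <- ifelse(groups == "atypical", "II", "I")
  recurrence <- stats::rbinom(n, 1, config$recur_prob[groups]) == 1
  samples <- data.frame(sample_id = ids, group = groups, grade = grade,
                        recurrence = recurrence, stringsAsFactors = FALSE)

  mets <- marker_metabolites()
  truth <- matrix(NA_real_, n, length(mets), dimnames = list(ids, mets))
  for (m in mets) {
    truth[, m] <- pmax(stats::rnorm(n, config$metab_means[groups, m],
                                    config$metab_sds[groups, m]), 1e-6)
  }

  lib <- default_peak_library()
  spectra <- lapply(seq_len(n), function(i) {
    lv <- c(truth[i, ], config$background_levels)
    synth_spectrum(lv, lib, noise_sd = config$spectrum_noise_sd,
                   n_points = config$n_spectrum_points, sample_id = ids[i])
  })
  names(spectra) <- ids

  probes_fish <- colnames(config$fish_alteration_fracs)
  n_regions <- 4L
  per_probe <- n_regions * config$nuclei_per_region
  fish <- expand.grid(nucleus = seq_len(config$nuclei_per_region),
                      region = seq_len(n_regions), probe = probes_fish,
                      sample_id = ids, stringsAsFactors = FALSE)
  frac <- config$fish_alteration_fracs[
    cbind(samples$group[match(fish$sample_id, ids)], fish$probe)]
  deleted <- stats::rbinom(nrow(fish), 1, frac) == 1
  fish_counts <- data.frame(sample_id = fish$sample_id, probe = fish$probe,
                            region = fish$region,
                            test_signals = ifelse(deleted, 1L, 2L),
                            control_signals = 2L, stringsAsFactors = FALSE)

  probe_ids <- sprintf("P%04d_at", seq_len(config$n_probes))
  planted <- probe_ids[seq_len(config$n_planted_de)]
  base <- stats::rnorm(config$n_probes, 7, 1)
  sign <- sample(c(-1, 1), config$n_planted_de, replace = TRUE)
  delta <- numeric(config$n_probes)
  delta[seq_len(config$n_planted_de)] <- sign * config$de_log2_effect
  shift <- c(benignA = 0, benignB = 1, atypical = 1.5)
  expr <- matrix(stats::rnorm(config$n_probes * n, 0, config$expr_noise_sd),
                 config$n_probes, n, dimnames = list(probe_ids, ids))
  expr <- expr + base + outer(delta, shift[groups])

  ct_genes <- planted[seq_len(min(3L, length(planted)))]
  ct_rows <- expand.grid(gene = ct_genes, sample_id = ids,
                         stringsAsFactors = FALSE)
  ct_val <- config$ct_intercept - expr[cbind(ct_rows$gene, ct_rows$sample_id)] +
    stats::rnorm(nrow(ct_rows), 0, config$ct_noise_sd)
  ct_table <- rbind(
    data.frame(sample_id = ct_rows$sample_id,
               group = groups[match(ct_rows$sample_id, ids)],
               gene = ct_rows$gene, ct = ct_val, stringsAsFactors = FALSE),
    data.frame(sample_id = ids, group = groups, gene = "GAPDH", ct = 20,
               stringsAsFactors = FALSE))

  structure(list(samples = samples, metabolite_truth = truth,
                 spectra = spectra, fish_counts = fish_counts,
                 expression = expr, planted_de_ids = planted,
                 ct_table = ct_table, true_labels = groups,
                 config = config),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(
    "Synthetic meningioma cohort: %d samples (%d benignA, %d benignB, %d atypical)\n",
    nrow(x$samples), sum(x$true_labels == "benignA"),
    sum(x$true_labels == "benignB"), sum(x$true_labels == "atypical")))
  cat(sprintf("%d probes (%d planted DE), %d FISH nuclei rows, seed %d\n",
              nrow(x$expression), length(x$planted_de_ids),
              nrow(x$fish_counts), x$config$seed))
  invisible(x)
}

#' Write a cohort bundle to a directory of TSV files
#'
#' Writes samples.tsv, metabolites.tsv, fish_counts.tsv, expression.tsv,
#' ct.tsv, one two-column ppm/intensity TSV per sample under spectra/, and
#' a manifest.json recording the configuration and seed. All tables are
#' UTF-8, tab-delimited, with a header row, decimal points and no quoting.
#'
#' @param bundle A \code{"cohort_bundle"}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "spectra"), showWarnings = FALSE)
  write_tsv(bundle$samples, file.path(dir, "samples.tsv"))
  met <- data.frame(sample_id = rownames(bundle$metabolite_truth),
                    bundle$metabolite_truth, stringsAsFactors = FALSE)
  write_tsv(met, file.path(dir, "metabolites.tsv"))
  write_tsv(bundle$fish_counts, file.path(dir, "fish_counts.tsv"))
  write_expression_tsv(bundle$expression, file.path(dir, "expression.tsv"))
  write_tsv(bundle$ct_table, file.path(dir, "ct.tsv"))
  for (id in names(bundle$spectra)) {
    sp <- bundle$spectra[[id]]
    write_tsv(data.frame(ppm = sp$ppm, intensity = sp$intensity),
              file.path(dir, "spectra", paste0(id, ".tsv")))
  }
  manifest <- list(package = "meningsub",
                   version = as.character(utils::packageVersion("meningsub")),
                   seed = bundle$config$seed,
                   config = unclass(bundle$config),
                   planted_de_ids = bundle$planted_de_ids)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor")
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing the cohort TSV files.
#' @return A list with the same components as a \code{"cohort_bundle"}
#'   (config fields as plain lists from the manifest).
#' @export
read_cohort <- function(dir) {
  samples <- read_tsv(file.path(dir, "samples.tsv"))
  samples$recurrence <- as.logical(samples$recurrence)
  met <- read_tsv(file.path(dir, "metabolites.tsv"))
  truth <- as.matrix(met[, -1, drop = FALSE])
  rownames(truth) <- met$sample_id
  fish_counts <- read_tsv(file.path(dir, "fish_counts.tsv"))
  fish_counts$probe <- as.character(fish_counts$probe)
  expr <- read_expression_tsv(file.path(dir, "expression.tsv"))
  ct_table <- read_tsv(file.path(dir, "ct.tsv"))
  spec_files <- list.files(file.path(dir, "spectra"), pattern = "\\.tsv$",
                           full.names = TRUE)
  spectra <- lapply(spec_files, function(f) {
    d <- read_tsv(f)
    nmr_spectrum(d$ppm, d$intensity,
                 sample_id = sub("\\.tsv$", "", basename(f)))
  })
  names(spectra) <- vapply(spectra, function(s) s$sample_id, character(1))
  spectra <- spectra[samples$sample_id]
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL
  list(samples = samples, metabolite_truth = truth, spectra = spectra,
       fish_counts = fish_counts, expression = expr, ct_table = ct_table,
       true_labels = samples$group,
       planted_de_ids = manifest$planted_de_ids,
       manifest = manifest)
}
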