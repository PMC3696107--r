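#' Marker metabolites used for metabolic aggressiveness
#'
#' Choline, lactate, taurine and fatty acids: elevated levels of these four
#' resonances mark high membrane turnover, anaerobic energy metabolism and
#' apoptosis resistance in meningioma tissue.
#'
#' @return Character vector of the four marker metabolite names.
#' @export
marker_metabolites <- function() {
  c("choline", "lactate", "taurine", "fatty_acids")
}

#' Build the atypical reference from metabolite profiles
#'
#' Computes, per marker metabolite, the sample mean and sample standard
#' deviation (n-1 denominator) of relative levels across the atypical
#' (WHO grade II) samples. The resulting intervals (mean +/- 2 SD) define
#' "atypical-like" metabolite levels for the benignB rule. A sample missing
#' a metabolite is excluded from that metabolite's statistics only; per-
#' metabolite sample counts are tracked.
#'
#' @param atypical_profiles A data frame or matrix (rows = samples,
#'   columns = metabolites, NA = missing) of relative levels, or a list of
#'   \code{"metabolite_profile"} objects as returned by
#'   [quantify_metabolites()].
#' @param metabolites Metabolites to include (default the four markers).
#' @return Object of class \code{"atypical_reference"}: list with
#'   \code{mean}, \code{sd}, \code{n} (named numeric vectors per
#'   metabolite) and \code{n_atypical} (number of input samples).
#' @export
build_reference <- function(atypical_profiles,
                            metabolites = marker_metabolites()) {
  m <- profiles_to_matrix(atypical_profiles, metabolites)
  if (nrow(m) < 2) stop("need at least 2 atypical samples")
  usable <- rowSums(!is.na(m)) > 0
  if (sum(usable) < 2) stop("fewer than 2 usable atypical samples")
  mu <- apply(m, 2, function(v) mean(v, na.rm = TRUE))
  sdev <- apply(m, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 2) stats::sd(v) else NA_real_
  })
  n <- apply(m, 2, function(v) sum(!is.na(v)))
  structure(list(mean = mu, sd = sdev, n = n, n_atypical = nrow(m),
                 metabolites = metabolites),
            class = "atypical_reference")
}

#' @export
print.atypical_reference <- function(x, ...) {
  cat(sprintf("Atypical reference (%d samples):\n", x$n_atypical))
  print(data.frame(metabolite = x$metabolites, mean = x$mean[x$metabolites],
                   sd = x$sd[x$metabolites], n = x$n[x$metabolites]),
        row.names = FALSE)
  invisible(x)
}

# Accept either a samples x metabolites table or a list of
# metabolite_profile objects; returns a numeric matrix with NA for missing.
profiles_to_matrix <- function(profiles, metabolites) {
  if (is.list(profiles) && !is.data.frame(profiles) &&
      all(vapply(profiles, inherits, logical(1), "metabolite_profile"))) {
    m <- t(vapply(profiles, function(p) {
      v <- p$levels[metabolites]
      names(v) <- metabolites
      v
    }, numeric(length(metabolites))))
    rownames(m) <- vapply(profiles, function(p) p$sample_id, character(1))
    return(m)
  }
  m <- as.matrix(as.data.frame(profiles))
  missing_cols <- setdiff(metabolites, colnames(m))
  if (length(missing_cols)) {
    stop("profiles lack metabolites: ", paste(missing_cols, collapse = ", "))
  }
  m[, metabolites, drop = FALSE]
}

#' Evaluate metabolic aggressiveness against the atypical reference
#'
#' A marker metabolite is "in range" when its relative level lies within
#' \code{sd_multiplier} standard deviations of the atypical reference mean,
#' inclusive on both boundaries. The sample is metabolically aggressive when
#' at least \code{markers_required} of the markers are in range (default:
#' three out of four). Missing markers (including fits that failed QC) count
#' as not-in-range and are flagged.
#'
#' @param profile Named numeric vector of relative levels, or a
#'   \code{"metabolite_profile"} object.
#' @param ref An \code{"atypical_reference"} from [build_reference()].
#' @param markers_required Minimum markers in range (default 3).
#' @param sd_multiplier Half-width of the interval in SDs (default 2).
#' @return List with \code{n_markers_in_range}, \code{aggressive},
#'   \code{in_range} (named logical) and \code{missing} (character).
#' @export
metabolic_aggressiveness <- function(profile, ref, markers_required = 3L,
                                     sd_multiplier = 2) {
  stopifnot(inherits(ref, "atypical_reference"))
  levels <- if (inherits(profile, "metabolite_profile")) profile$levels else profile
  markers <- ref$metabolites
  in_range <- stats::setNames(logical(length(markers)), markers)
  for (m in markers) {
    lv <- levels[[m]]
    if (is.null(lv) || is.na(lv) || is.na(ref$mean[[m]]) || is.na(ref$sd[[m]])) next
    lo <- ref$mean[[m]] - sd_multiplier * ref$sd[[m]]
    hi <- ref$mean[[m]] + sd_multiplier * ref$sd[[m]]
    in_range[m] <- lv >= lo && lv <= hi
  }
  missing <- markers[vapply(markers, function(m) {
    lv <- levels[[m]]
    is.null(lv) || is.na(lv)
  }, logical(1))]
  n_in <- sum(in_range)
  list(n_markers_in_range = n_in,
       aggressive = n_in >= markers_required,
       in_range = in_range,
       missing = missing)
}

#' Classify one sample into benignA / benignB / atypical
#'
#' Implements the molecular subgrouping rule for meningioma. WHO grade II
#' samples are atypical by grade precedence. A grade I sample is benignB
#' when it carries chromosomal abnormalities beyond monosomy 22 (detected by
#' FISH or karyotyping) and/or shows atypical-like levels for at least three
#' of the four marker metabolites; grade I samples fulfilling neither
#' criterion are benignA. The two evidence streams are an inclusive OR:
#' either suffices, so samples lacking a karyotype can still be classified
#' through the metabolic arm (and vice versa).
#'
#' @param grade WHO grade, \code{"I"} or \code{"II"}.
#' @param karyo A \code{"karyotype_summary"} or NULL when no cytogenetic
#'   data exist.
#' @param profile Metabolite profile (named vector or
#'   \code{"metabolite_profile"}) or NULL.
#' @param ref An \code{"atypical_reference"}; required when \code{profile}
#'   is supplied.
#' @param markers_required,sd_multiplier Passed to
#'   [metabolic_aggressiveness()].
#' @return Object of class \code{"subgroup_label"}: list with \code{label}
#'   and \code{evidence} (\code{chromosomal}, \code{metabolic},
#'   \code{n_markers_in_range}).
#' @export
classify_sample <- function(grade, karyo = NULL, profile = NULL, ref = NULL,
                            markers_required = 3L, sd_multiplier = 2) {
  grade <- as.character(grade)
  if (!grade %in% c("I", "II")) stop("grade must be 'I' or 'II'")
  if (grade == "II") {
    return(structure(list(label = "atypical",
                          evidence = list(chromosomal = NA, metabolic = NA,
                                          n_markers_in_range = NA_integer_)),
                     class = "subgroup_label"))
  }
  has_karyo <- !is.null(karyo) && karyo$source != "none"
  has_metab <- !is.null(profile) && !is.null(ref)
  if (!has_karyo && !has_metab) {
    stop("unclassifiable: neither cytogenetic nor metabolite data available")
  }
  chromosomal <- if (has_karyo) isTRUE(karyo$abnormal_beyond_22) else FALSE
  n_in <- NA_integer_
  metabolic <- FALSE
  if (has_metab) {
    agg <- metabolic_aggressiveness(profile, ref, markers_required,
                                    sd_multiplier)
    metabolic <- agg$aggressive
    n_in <- agg$n_markers_in_range
  }
  label <- if (chromosomal || metabolic) "benignB" else "benignA"
  structure(list(label = label,
                 evidence = list(chromosomal = chromosomal,
                                 metabolic = metabolic,
                                 n_markers_in_range = n_in)),
            class = "subgroup_label")
}

#' @export
print.subgroup_label <- function(x, ...) {
  ev <- x$evidence
  cat(sprintf("%s (chromosomal: %s, metabolic: %s, markers in range: %s)\n",
              x$label, ev$chromosomal, ev$metabolic, ev$n_markers_in_range))
  invisible(x)
}

#' Classify a cohort of samples
#'
#' Vector wrapper around [classify_sample()]; builds the atypical reference
#' from the grade II samples of the cohort itself unless a fixed reference
#' is supplied.
#'
#' @param metadata Data frame with columns \code{sample_id} and
#'   \code{grade}.
#' @param karyos Named list of \code{"karyotype_summary"} objects (names =
#'   sample ids; missing entries allowed).
#' @param profiles Samples x metabolites table (rownames = sample ids) or
#'   named list of \code{"metabolite_profile"} objects.
#' @param ref Optional fixed \code{"atypical_reference"}; default builds it
#'   from the grade II rows of \code{profiles}.
#' @param markers_required,sd_multiplier Passed through.
#' @return Data frame: sample_id, label, chromosomal_evidence,
#'   metabolic_evidence, n_markers_in_range.
#' @export
classify_cohort <- function(metadata, karyos = NULL, profiles = NULL,
                            ref = NULL, markers_required = 3L,
                            sd_multiplier = 2) {
  stopifnot(all(c("sample_id", "grade") %in% names(metadata)))
  prof_mat <- NULL
  if (!is.null(profiles)) {
    prof_mat <- profiles_to_matrix(profiles, marker_metabolites())
  }
  if (is.null(ref) && !is.null(prof_mat)) {
    atyp_ids <- metadata$sample_id[metadata$grade == "II"]
    atyp_ids <- intersect(atyp_ids, rownames(prof_mat))
    if (length(atyp_ids) >= 2) {
      ref <- build_reference(prof_mat[atyp_ids, , drop = FALSE])
    }
  }
  rows <- lapply(seq_len(nrow(metadata)), function(i) {
    sid <- metadata$sample_id[i]
    karyo <- if (!is.null(karyos)) karyos[[sid]] else NULL
    profile <- if (!is.null(prof_mat) && sid %in% rownames(prof_mat)) {
      prof_mat[sid, ]
    } else NULL
    lab <- classify_sample(metadata$grade[i], karyo, profile, ref,
                           markers_required, sd_multiplier)
    data.frame(sample_id = sid, label = lab$label,
               chromosomal_evidence = lab$evidence$chromosomal,
               metabolic_evidence = lab$evidence$metabolic,
               n_markers_in_range = lab$evidence$n_markers_in_range,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
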