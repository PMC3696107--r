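#' Classify a single nucleus from FISH signal counts
#'
#' Applies the per-nucleus deletion rule for locus-specific FISH probes
#' scored against a control probe: a nucleus is deleted when it shows fewer
#' test signals than control signals (ratios 0/1, 0/2, 1/2, 1/3, ...) or at
#' most one test signal in the presence of any control signal; the balanced
#' disomic pattern (2/2) is normal. Gains/polysomies are outside the calling
#' rules and score as normal. A nucleus with no signal on either probe is
#' uninformative and is excluded from fraction denominators.
#'
#' @param test_signals,control_signals Non-negative integer vectors
#'   (recycled to common length) of signal counts per nucleus.
#' @return Character vector with values \code{"deleted"}, \code{"normal"} or
#'   \code{"uninformative"}.
#' @export
classify_nucleus <- function(test_signals, control_signals) {
  if (any(test_signals < 0) || any(control_signals < 0)) {
    stop("signal counts must be non-negative")
  }
  n <- max(length(test_signals), length(control_signals))
  t <- rep_len(test_signals, n)
  ctl <- rep_len(control_signals, n)
  out <- rep("normal", n)
  out[t < ctl | (t <= 1 & ctl >= 1)] <- "deleted"
  out[t == 0 & ctl == 0] <- "uninformative"
  out
}

#' Call a chromosomal deletion from nuclei counts for one probe
#'
#' Classifies every scored nucleus, computes the fraction of informative
#' nuclei carrying the deletion pattern and calls a deletion when that
#' fraction strictly exceeds the cutoff. The default cutoff of 0.20 is the
#' generic >20\% rule; a control-derived cutoff from [derive_cutoff()] can
#' be supplied instead. Region structure is bookkeeping only: calls depend
#' on the pooled counts.
#'
#' @param counts Data frame with one row per nucleus and columns
#'   \code{test_signals} and \code{control_signals} (columns
#'   \code{sample_id}, \code{probe}, \code{region} are carried through if
#'   present but not used for calling).
#' @param cutoff Fraction above which a deletion is called (strict
#'   inequality). Default 0.20.
#' @param min_informative Minimum informative nuclei required (default 50).
#' @return Object of class \code{"alteration_call"}: list with
#'   \code{probe}, \code{abnormal_fraction}, \code{cutoff_used},
#'   \code{status} (\code{"deletion"} or \code{"normal"}),
#'   \code{n_informative} and \code{n_uninformative}.
#' @export
call_probe <- function(counts, cutoff = 0.20, min_informative = 50L) {
  if (!all(c("test_signals", "control_signals") %in% names(counts))) {
    stop("'counts' needs columns test_signals and control_signals")
  }
  n_total <- nrow(counts)
  if (n_total < 100 || n_total > 200) {
    warning(sprintf("%d nuclei scored; 100-200 preferred", n_total))
  }
  cls <- classify_nucleus(counts$test_signals, counts$control_signals)
  informative <- cls != "uninformative"
  n_inf <- sum(informative)
  if (n_inf < min_informative) {
    stop(sprintf("only %d informative nuclei (need >= %d)",
                 n_inf, min_informative))
  }
  frac <- sum(cls == "deleted") / n_inf
  probe <- if ("probe" %in% names(counts)) as.character(counts$probe[1]) else NA_character_
  structure(list(probe = probe,
                 abnormal_fraction = frac,
                 cutoff_used = cutoff,
                 status = if (frac > cutoff) "deletion" else "normal",
                 n_informative = n_inf,
                 n_uninformative = n_total - n_inf),
            class = "alteration_call")
}

#' @export
print.alteration_call <- function(x, ...) {
  cat(sprintf("Probe %s: %.1f%% abnormal nuclei (cutoff %.1f%%) -> %s\n",
              x$probe, 100 * x$abnormal_fraction, 100 * x$cutoff_used,
              x$status))
  invisible(x)
}

#' Derive a deletion cutoff from non-neoplastic control fractions
#'
#' Cutoffs for deletion calls are anchored to the frequencies of the
#' deletion signal pattern for the same probe in non-neoplastic control
#' tissue: median plus three standard deviations, floored at zero.
#'
#' @param control_fractions Numeric vector (length >= 3) of abnormal-nuclei
#'   fractions observed in control tissue.
#' @return The cutoff fraction.
#' @examples
#' derive_cutoff(c(0.05, 0.06, 0.07, 0.08, 0.09))  # ~0.117
#' @export
derive_cutoff <- function(control_fractions) {
  if (length(control_fractions) < 3) {
    stop("need at least 3 control fractions")
  }
  if (any(!is.finite(control_fractions)) || any(control_fractions < 0)) {
    stop("control fractions must be finite and non-negative")
  }
  max(0, stats::median(control_fractions) + 3 * stats::sd(control_fractions))
}

#' Summarize cytogenetic abnormality for one sample
#'
#' Combines deletion calls from FISH with (optional) conventional karyotype
#' findings into a per-sample summary. The chromosomal arm of the benignB
#' classification rule keys on \code{abnormal_beyond_22}: monosomy 22 as the
#' only alteration is the canonical meningioma change and is tolerated
#' within benignA.
#'
#' @param fish_calls List of \code{"alteration_call"} objects (possibly
#'   empty or NULL when no FISH data exist).
#' @param karyotype_alterations Character vector of altered-chromosome
#'   labels from karyotyping (e.g. \code{c("1p", "22")}), or NULL when no
#'   karyotype was obtained.
#' @param sample_id Sample identifier carried into the summary.
#' @return Object of class \code{"karyotype_summary"}: list with
#'   \code{sample_id}, \code{alterations} (character set),
#'   \code{has_any_alteration}, \code{abnormal_beyond_22} and \code{source}
#'   (\code{"fish"}, \code{"karyotype"}, \code{"both"} or \code{"none"}).
#' @export
summarize_karyotype <- function(fish_calls = NULL, karyotype_alterations = NULL,
                                sample_id = NA_character_) {
  has_fish <- !is.null(fish_calls) && length(fish_calls) > 0
  has_karyo <- !is.null(karyotype_alterations)
  fish_alt <- character(0)
  if (has_fish) {
    del <- vapply(fish_calls, function(a) a$status == "deletion", logical(1))
    fish_alt <- vapply(fish_calls, function(a) a$probe, character(1))[del]
  }
  alterations <- sort(unique(c(fish_alt, as.character(karyotype_alterations))))
  source <- if (has_fish && has_karyo) "both"
            else if (has_fish) "fish"
            else if (has_karyo) "karyotype"
            else "none"
  structure(list(sample_id = sample_id,
                 alterations = alterations,
                 has_any_alteration = length(alterations) > 0,
                 abnormal_beyond_22 = length(setdiff(alterations, "22")) > 0,
                 source = source),
            class = "karyotype_summary")
}

#' @export
print.karyotype_summary <- function(x, ...) {
  alt <- if (length(x$alterations)) paste(x$alterations, collapse = ", ") else "none"
  cat(sprintf("Sample %s [%s]: alterations {%s}; beyond chr22: %s\n",
              x$sample_id, x$source, alt, x$abnormal_beyond_22))
  invisible(x)
}
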