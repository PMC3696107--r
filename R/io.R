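#' Write a data frame as a plain TSV
#'
#' UTF-8, tab-delimited, header row, decimal points, no quoting.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a plain TSV written by [write_tsv()]
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

#' Write a log2 expression matrix as TSV
#'
#' First column \code{probeset_id}, remaining columns one per sample.
#'
#' @param matrix Probes x samples numeric matrix with dimnames.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- data.frame(probeset_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a log2 expression matrix from TSV
#'
#' @param path Input path (first column probeset_id, then samples).
#' @return Numeric matrix, probes x samples.
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m))) stop("duplicate probeset ids in ", path)
  m
}

# Parse a numeric column that may carry decimal commas and censored
# entries like "<0.0001" (taken at their bound, flagged by the caller).
parse_numeric_loose <- function(x) {
  x <- gsub(",", ".", trimws(x))
  x <- gsub("−", "-", x)  # unicode minus
  censored <- grepl("^<", x)
  x <- sub("^<", "", x)
  v <- suppressWarnings(as.numeric(x))
  attr(v, "censored") <- censored
  v
}

#' Load a Table-1-style differential-expression TSV
#'
#' Parses a tab-separated table with columns Probeset ID, Gene Title, Gene
#' Symbol, Chromosomal Location, p-value, FDR and FC. Decimal commas are
#' normalized to points, unicode minus signs to ASCII, missing annotations
#' (en dash or \code{-}) to NA, and censored p-values such as
#' \code{<0.0001} are taken at their bound with a \code{p_censored} flag.
#'
#' @param path Path to the TSV.
#' @return A \code{c("de_table", "data.frame")} with columns probeset_id,
#'   gene_title, gene_symbol, chromosomal_location, p_value, fdr,
#'   fold_change, p_censored.
#' @export
load_de_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (ncol(df) < 7) stop("malformed DE table (expected 7 columns): ", path)
  names(df)[1:7] <- c("probeset_id", "gene_title", "gene_symbol",
                      "chromosomal_location", "p_value", "fdr", "fold_change")
  for (col in c("gene_title", "gene_symbol", "chromosomal_location")) {
    df[[col]] <- trimws(df[[col]])
    df[[col]][df[[col]] %in% c("-", "–", "—", "")] <- NA_character_
  }
  p <- parse_numeric_loose(df$p_value)
  df$p_value <- as.numeric(p)
  df$p_censored <- attr(p, "censored")
  df$fdr <- as.numeric(parse_numeric_loose(df$fdr))
  df$fold_change <- as.numeric(parse_numeric_loose(df$fold_change))
  bad <- which(is.na(df$p_value) | is.na(df$fdr) | is.na(df$fold_change))
  if (length(bad) > 0) {
    stop("malformed DE table at data line ", bad[1] + 1, " of ", path)
  }
  structure(df, class = c("de_table", "data.frame"))
}

#' Load the packaged benignA-vs-benignB differential-expression table
#'
#' The 59 probe sets retained by the combined filter (|FC| >= 2, p < 0.005,
#' BH FDR <= 0.005) in the benignA-vs-benignB contrast, as published:
#' 13 probe sets higher in benignA (positive FC, led by HOXB3 at 9.89) and
#' 46 higher in benignB (negative FC, down to -21.05 for the unannotated
#' probe set 230781_at). The FDR column reflects adjustment over the full
#' array (~54,675 probe sets) and is shipped as given data, not
#' recomputable from these 59 rows.
#'
#' @return A \code{c("de_table", "data.frame")} of 59 records.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_benignA_vs_benignB.tsv",
                      package = "meningsub")
  if (path == "") stop("packaged fixture not found")
  load_de_table(path)
}

#' Pipeline configuration
#'
#' Collects the thresholds and paths consumed by [run_pipeline()]. With
#' \code{simulate = TRUE} the pipeline generates its own cohort from
#' \code{sim} before analyzing it.
#'
#' @param input_dir Cohort directory (as written by [write_cohort()]), or
#'   NULL when simulating.
#' @param simulate Generate a synthetic cohort instead of reading one.
#' @param sim A \code{"sim_config"} used when simulating.
#' @param output_dir Directory for result tables.
#' @param fc_min,p_max,fdr_max Differential-expression filter thresholds.
#' @param fish_cutoff Deletion-call cutoff fraction (default 0.20; supply a
#'   control-derived value from [derive_cutoff()] to override).
#' @param markers_required,sd_multiplier Subgrouping rule parameters.
#' @param quantify_spectra Quantify metabolites from the spectra (TRUE) or
#'   use the metabolite table directly (FALSE).
#' @param seed Seed recorded in the manifest and used for simulation.
#' @return Validated list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(input_dir = NULL, simulate = is.null(input_dir),
                            sim = sim_config(seed = seed),
                            output_dir = tempfile("meningsub_run_"),
                            fc_min = 2, p_max = 0.005, fdr_max = 0.005,
                            fish_cutoff = 0.20, markers_required = 3L,
                            sd_multiplier = 2, quantify_spectra = FALSE,
                            seed = 1L) {
  if (fc_min <= 0 || p_max <= 0 || fdr_max <= 0 || fish_cutoff <= 0) {
    stop("thresholds must be positive")
  }
  if (markers_required > length(marker_metabolites())) {
    stop("markers_required exceeds the number of marker metabolites")
  }
  if (!simulate && is.null(input_dir)) {
    stop("either enable simulation or provide an input directory")
  }
  structure(list(input_dir = input_dir, simulate = simulate, sim = sim,
                 output_dir = output_dir, fc_min = fc_min, p_max = p_max,
                 fdr_max = fdr_max, fish_cutoff = fish_cutoff,
                 markers_required = as.integer(markers_required),
                 sd_multiplier = sd_multiplier,
                 quantify_spectra = quantify_spectra,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end subgrouping pipeline
#'
#' Simulates or reads a cohort, derives metabolite profiles (true levels or
#' quantified from the spectra), calls FISH deletions per sample and probe,
#' builds the atypical metabolite reference, classifies grade I samples
#' into benignA/benignB, runs the combined differential-expression filter
#' between the subgroups, clusters samples over the selected probes,
#' associates subgroup with recurrence by the exact Fisher test, and
#' summarizes ddCt relative expression for the Ct-table genes. All result
#' tables plus a machine-readable manifest are written to the output
#' directory; rerunning with the same config and seed reproduces identical
#' outputs.
#'
#' @param config A \code{"pipeline_config"}.
#' @return Object of class \code{"pipeline_result"}: list with
#'   \code{labels}, \code{de}, \code{clustering}, \code{recurrence},
#'   \code{ddct}, \code{profiles}, \code{cohort} and \code{output_dir}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  cohort <- stage("input", {
    if (config$simulate) simulate_cohort(config$sim)
    else read_cohort(config$input_dir)
  })
  samples <- cohort$samples

  profiles <- stage("metabolite_profiles", {
    if (config$quantify_spectra) {
      m <- t(vapply(cohort$spectra,
                    function(s) quantify_metabolites(s)$levels[marker_metabolites()],
                    numeric(4)))
      colnames(m) <- marker_metabolites()
      m[samples$sample_id, , drop = FALSE]
    } else {
      cohort$metabolite_truth[samples$sample_id, marker_metabolites(),
                              drop = FALSE]
    }
  })

  karyos <- stage("fish_calls", {
    out <- list()
    for (sid in samples$sample_id) {
      sub <- cohort$fish_counts[cohort$fish_counts$sample_id == sid, ,
                                drop = FALSE]
      calls <- lapply(split(sub, sub$probe), function(d) {
        suppressWarnings(call_probe(d, cutoff = config$fish_cutoff))
      })
      out[[sid]] <- summarize_karyotype(calls, sample_id = sid)
    }
    out
  })

  labels <- stage("classification", {
    classify_cohort(samples, karyos, profiles,
                    markers_required = config$markers_required,
                    sd_multiplier = config$sd_multiplier)
  })

  de <- stage("differential_expression", {
    benign <- labels$sample_id[labels$label %in% c("benignA", "benignB")]
    expr <- cohort$expression[, benign, drop = FALSE]
    select_de(expr, labels$label[match(benign, labels$sample_id)],
              ref_level = "benignA", fc_min = config$fc_min,
              p_max = config$p_max, fdr_max = config$fdr_max)
  })

  clustering <- stage("clustering", {
    if (nrow(de) >= 2) {
      hierarchical_cluster(
        cohort$expression[de$probeset_id, samples$sample_id, drop = FALSE])
    } else NULL
  })

  recurrence <- stage("recurrence", {
    recurrence_summary(labels$label, samples$recurrence)
  })

  ddct <- stage("ddct", {
    genes <- setdiff(unique(cohort$ct_table$gene), "GAPDH")
    res <- lapply(genes, function(g) {
      r <- ddct_fold_change(cohort$ct_table, g, control_group = "benignA")
      ab <- r$per_sample[r$per_sample$group %in% c("benignA", "benignB"), ]
      p <- mann_whitney_exact(ab$rel_expr[ab$group == "benignA"],
                              ab$rel_expr[ab$group == "benignB"])
      cbind(r$per_group, gene = g, mw_p_benignA_vs_benignB = round(p, 3))
    })
    do.call(rbind, res)
  })

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(labels, file.path(config$output_dir, "labels.tsv"))
  write_tsv(as.data.frame(de), file.path(config$output_dir, "de.tsv"))
  if (!is.null(clustering)) {
    write_tsv(data.frame(position = seq_along(clustering$leaf_order),
                         sample_id = clustering$leaf_order),
              file.path(config$output_dir, "cluster_leaf_order.tsv"))
  }
  rec_out <- cohort$samples[0, 0]
  write_tsv(cbind(recurrence$rates,
                  fisher_p = round(recurrence$p_value, 3)),
            file.path(config$output_dir, "recurrence.tsv"))
  write_tsv(ddct, file.path(config$output_dir, "ddct.tsv"))
  manifest <- list(package = "meningsub",
                   version = as.character(utils::packageVersion("meningsub")),
                   r_version = as.character(getRversion()),
                   seed = config$seed,
                   config = unclass(config)[setdiff(names(config), "sim")],
                   sim = if (config$simulate) unclass(config$sim) else NULL)
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor", null = "null")
  structure(list(labels = labels, de = de, clustering = clustering,
                 recurrence = recurrence, ddct = ddct, profiles = profiles,
                 cohort = cohort, output_dir = config$output_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  tab <- table(x$labels$label)
  cat("meningsub pipeline result\n")
  cat("Subgroups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("Differentially expressed probe sets: %d\n", nrow(x$de)))
  cat(sprintf("Recurrence benignA-vs-benignB Fisher p = %.3f\n",
              x$recurrence$p_value))
  cat("Outputs in:", x$output_dir, "\n")
  invisible(x)
}
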