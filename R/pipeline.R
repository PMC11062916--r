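#' Pipeline configuration
#'
#' One document holding every threshold and convention used by
#' [run_pipeline()]; the full configuration (and its hash) is echoed into
#' the audit block of every output.
#'
#' @param alpha FDR threshold for DE significance (default 0.05).
#' @param expression_floor Minimum mean log2 normalized expression for a DE
#'   call (default 1.0).
#' @param fold_change_threshold Minimum tumour-versus-normal fold change on
#'   the linear scale (default 1.5).
#' @param windows_kb Graded upstream window sizes in kb (default
#'   `c(1, 2, 5, 10)`).
#' @param max_distance_intergenic,max_distance_intronic TSS-distance rule
#'   limits in bp (defaults 2000 and 4000).
#' @param driver_cutoffs Optional fixed driver cutoffs (one or two values,
#'   e.g. 12.288 for a high/low split); `NULL` (default) stratifies by
#'   tertiles.
#' @param min_votes Target-prediction consensus votes required (default 2).
#' @param exclusions miRNAs excluded from the final list as already
#'   well-known regulators.
#' @param de_mode `"significant"` (FDR and expression floor) or
#'   `"fdr_only"`.
#' @param min_overlap_bp Minimum peak/window overlap to count as bound
#'   (default 1).
#' @param max_clinical Number of top-ranked candidates run through clinical
#'   association (default 10).
#' @param seed Seed recorded in the audit block (the pipeline itself draws
#'   no random numbers; this documents the generator seed of the inputs).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.05,
                            expression_floor = 1.0,
                            fold_change_threshold = 1.5,
                            windows_kb = c(1, 2, 5, 10),
                            max_distance_intergenic = 2000,
                            max_distance_intronic = 4000,
                            driver_cutoffs = NULL,
                            min_votes = 2,
                            exclusions = character(),
                            de_mode = c("significant", "fdr_only"),
                            min_overlap_bp = 1,
                            max_clinical = 10,
                            seed = 1) {
  de_mode <- match.arg(de_mode)
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  x <- unclass(config)
  x <- x[order(names(x))]
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                           null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}

#' Run the full prioritization pipeline
#'
#' Executes, in order: consensus peak intersection across ChIP replicates;
#' binding assignment at graded upstream windows; CPM/log2 normalization;
#' driver stratification (tertiles, or fixed cutoffs when configured);
#' differential expression between the top and bottom strata; cohort
#' fold-change filtering and consolidation; the candidate cascade; and
#' clinical-covariate association for the top-ranked candidates. All stages
#' are deterministic, so rerunning with the same inputs and config produces
#' byte-identical reports.
#'
#' @param study A [simulate_study()] bundle, a directory written by
#'   [write_simulation()], or any list with elements `annotation`, `chip`,
#'   `counts`, `driver`, `metadata`, `cohorts`.
#' @param config A [pipeline_config()].
#' @param output_dir If non-`NULL`, `candidates.tsv`, `records.tsv`,
#'   `de.tsv` and `audit.json` are written there.
#' @return An object of class `pipeline_result`: `binding`,
#'   `stratification`, `de`, `cohorts_unified`, `cascade`, `candidates`
#'   (with clinical flags), `clinical`, `audit`.
#' @export
run_pipeline <- function(study, config = pipeline_config(),
                         output_dir = NULL) {
  if (is.character(study)) study <- read_simulation(study)
  needed <- c("annotation", "chip", "counts", "driver", "metadata",
              "cohorts")
  for (part in needed) {
    if (is.null(study[[part]]))
      stop("pipeline input is missing '", part, "' (stage: ",
           switch(part, metadata = "stratification", chip = "consensus",
                  cohorts = "cohort consolidation", part),
           ")", call. = FALSE)
  }
  tf <- if (inherits(study$chip[[1]], "peak_set"))
    study$chip[[1]]$factor else "TF"

  consensus <- consensus_across_replicates(study$chip)
  binding <- assign_binding(study$annotation, consensus,
                            windows_kb = config$windows_kb, factor = tf,
                            min_overlap_bp = config$min_overlap_bp)

  norm <- normalize_log2(study$counts)
  strat <- if (is.null(config$driver_cutoffs))
    stratify_tertiles(study$driver, driver = tf)
  else
    stratify_by_cutoff(study$driver, config$driver_cutoffs, driver = tf)
  high <- names(strat$strata)[strat$strata == "H"]
  low <- names(strat$strata)[strat$strata == "L"]
  de <- differential_expression(norm, high, low, alpha = config$alpha,
                                expression_floor = config$expression_floor)

  calls <- lapply(study$cohorts, fold_change_filter,
                  threshold = config$fold_change_threshold)
  unified <- consolidate_cohorts(calls)

  rule <- distance_rule(config$max_distance_intergenic,
                        config$max_distance_intronic)
  cascade <- run_cascade(binding, de, unified, rule,
                         exclusions = config$exclusions,
                         de_mode = config$de_mode)

  cand <- cascade$candidates
  cand$gcnis_assoc <- NA
  cand$stage_assoc <- NA
  clinical <- list()
  top <- utils::head(seq_len(nrow(cand)), config$max_clinical)
  for (k in top) {
    ca <- clinical_association(norm, study$metadata, cand$mirna_id[k],
                               alpha = config$alpha)
    clinical[[cand$mirna_id[k]]] <- ca
    cand$gcnis_assoc[k] <- "gcnis_assoc" %in% ca$flags
    cand$stage_assoc[k] <- "stage_assoc" %in% ca$flags
  }

  audit <- list(
    config = unclass(config)[order(names(unclass(config)))],
    config_hash = config_hash(config),
    seed = config$seed,
    factor = tf,
    n_consensus_peaks = length(consensus),
    strata_sizes = as.list(table(strat$strata)),
    n_de_significant = sum(de$significant),
    n_cohort_unified = nrow(unified),
    stage_counts = as.list(cascade$stage_counts)
  )
  result <- structure(list(binding = binding, stratification = strat,
                           de = de, cohorts_unified = unified,
                           cascade = cascade, candidates = cand,
                           clinical = clinical, audit = audit,
                           consensus = consensus),
                      class = "pipeline_result")
  if (!is.null(output_dir)) write_pipeline_reports(result, output_dir)
  result
}

write_pipeline_reports <- function(result, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  write_tsv(result$candidates, p("candidates.tsv"))
  write_tsv(result$cascade$records, p("records.tsv"))
  write_tsv(as.data.frame(result$de), p("de.tsv"))
  jsonlite::write_json(result$audit, p("audit.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(output_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  consensus peaks: %d | DE significant: %d | cohort-unified: %d\n",
              x$audit$n_consensus_peaks, x$audit$n_de_significant,
              x$audit$n_cohort_unified))
  print(x$cascade)
  invisible(x)
}

#' @export
summary.pipeline_result <- function(object, ...) {
  cat("Integrative miRNA prioritization pipeline\n")
  cat("config hash:", object$audit$config_hash, "\n\n")
  summary(object$cascade)
  cand <- object$candidates
  flagged <- cand[!is.na(cand$gcnis_assoc) &
                    (cand$gcnis_assoc | cand$stage_assoc), "mirna_id"]
  if (length(flagged))
    cat("\nClinically associated candidates:",
        paste(flagged, collapse = " "), "\n")
  invisible(object)
}
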