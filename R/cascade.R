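#' TSS-distance rule by genomic class
#'
#' Intergenic miRNAs have their own promoters and their transcription start
#' sites are expected within ~2 kb upstream of the annotated locus; intronic
#' miRNAs, transcribed with their host, are allowed ~4 kb.
#'
#' @param max_distance_intergenic Maximum binding distance (bp) for
#'   intergenic loci, default 2000.
#' @param max_distance_intronic Maximum binding distance (bp) for intronic
#'   loci, default 4000.
#' @return A list of class `distance_rule`.
#' @export
distance_rule <- function(max_distance_intergenic = 2000,
                          max_distance_intronic = 4000) {
  stopifnot(max_distance_intergenic > 0, max_distance_intronic > 0)
  structure(list(max_distance_intergenic = max_distance_intergenic,
                 max_distance_intronic = max_distance_intronic),
            class = "distance_rule")
}

#' Apply the TSS-distance rule
#'
#' @param distance_bp Binding distance(s) to the locus 5' end (bp).
#' @param genomic_class Parallel vector, `"intergenic"` or `"intronic"`.
#' @param rule A [distance_rule()].
#' @return Logical vector.
#' @export
distance_rule_pass <- function(distance_bp, genomic_class,
                               rule = distance_rule()) {
  if (any(is.na(genomic_class) |
          !genomic_class %in% c("intergenic", "intronic")))
    stop("missing or unknown genomic_class", call. = FALSE)
  lim <- ifelse(genomic_class == "intergenic",
                rule$max_distance_intergenic, rule$max_distance_intronic)
  distance_bp <= lim
}

#' Run the candidate-prioritization cascade
#'
#' Turns the evidence layers into an auditable ranked candidate list:
#' \enumerate{
#'   \item keep miRNAs with consensus TF binding within the largest upstream
#'     window;
#'   \item intersect with miRNAs significantly differentially expressed in
#'     the driver high/low contrast;
#'   \item annotate cross-cohort (tumour-versus-normal) direction
#'     consistency;
#'   \item apply the genomic-class TSS-distance rule;
#'   \item drop miRNAs on the known-miRNA exclusion list
#'     (`excluded_reason = "known"`).
#' }
#' Tier 1 passes stages 1-4; tier 2 passes 1, 2 and 4 but not cohort
#' consistency; tier 3 passes only 1-2. Within a tier, candidates are sorted
#' by ascending DE FDR, then ascending binding distance.
#'
#' @param binding A [assign_binding()] table (must carry `genomic_class`).
#' @param de A [differential_expression()] table for the driver H/L
#'   contrast.
#' @param cohorts Unified cohort calls from [consolidate_cohorts()] (may be
#'   `NULL`: no miRNA is then cohort-consistent).
#' @param rule A [distance_rule()].
#' @param exclusions Character vector of miRNAs excluded as already
#'   well-known regulators.
#' @param de_mode `"significant"` uses the DE significance flag (FDR and
#'   expression floor); `"fdr_only"` ignores the expression floor.
#' @return An object of class `cascade_result`: `$candidates` (the ranked
#'   final list), `$records` (every input miRNA with its full evidence
#'   trail), `$stage_counts`.
#' @export
run_cascade <- function(binding, de, cohorts = NULL, rule = distance_rule(),
                        exclusions = character(), de_mode = c("significant",
                                                              "fdr_only")) {
  de_mode <- match.arg(de_mode)
  if (any(grepl("\\s", binding$mirna_id)))
    warning("possibly unharmonized ids (whitespace) in binding table",
            call. = FALSE)
  alpha <- attr(de, "alpha")
  if (is.null(alpha)) alpha <- 0.05
  rec <- data.frame(
    mirna_id = binding$mirna_id,
    bound = binding$bound,
    distance_bp = binding$distance_bp,
    genomic_class = binding$genomic_class,
    stringsAsFactors = FALSE
  )
  i <- match(rec$mirna_id, de$feature_id)
  rec$de_direction <- de$direction[i]
  rec$de_fdr <- de$fdr[i]
  de_pass <- if (de_mode == "significant") de$significant[i] else
    de$fdr[i] < alpha
  rec$de_significant <- !is.na(de_pass) & de_pass
  if (is.null(cohorts) || nrow(cohorts) == 0L) {
    rec$cohort_consistent <- FALSE
  } else {
    rec$cohort_consistent <- direction_consistency(rec$mirna_id,
                                                   rec$de_direction, cohorts)
  }
  rec$distance_pass <- rec$bound &
    distance_rule_pass(ifelse(is.na(rec$distance_bp), Inf, rec$distance_bp),
                       rec$genomic_class, rule)
  base <- rec$bound & rec$de_significant
  rec$tier <- ifelse(base & rec$distance_pass & rec$cohort_consistent, 1L,
                     ifelse(base & rec$distance_pass, 2L,
                            ifelse(base, 3L, NA_integer_)))
  rec$excluded_reason <- NA_character_
  rec$excluded_reason[!rec$bound] <- "not_bound"
  rec$excluded_reason[rec$bound & !rec$de_significant] <- "not_de"
  rec$excluded_reason[rec$mirna_id %in% exclusions & !is.na(rec$tier)] <-
    "known"
  cand <- rec[!is.na(rec$tier) & is.na(rec$excluded_reason), , drop = FALSE]
  cand <- cand[order(cand$tier, cand$de_fdr, cand$distance_bp,
                     cand$mirna_id), , drop = FALSE]
  rownames(cand) <- NULL
  stage_counts <- c(
    input = nrow(rec),
    bound = sum(rec$bound),
    bound_and_de = sum(base),
    cohort_consistent = sum(base & rec$cohort_consistent),
    distance_pass = sum(base & rec$distance_pass),
    tier1 = sum(cand$tier == 1L),
    tier2 = sum(cand$tier == 2L),
    tier3 = sum(cand$tier == 3L),
    excluded_known = sum(rec$excluded_reason == "known", na.rm = TRUE)
  )
  structure(list(candidates = cand, records = rec,
                 stage_counts = stage_counts, rule = rule,
                 exclusions = exclusions, de_mode = de_mode),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("<cascade_result>\n")
  sc <- x$stage_counts
  cat(sprintf("  %d miRNAs in -> %d bound -> %d bound+DE -> tiers %d/%d/%d (known excluded: %d)\n",
              sc[["input"]], sc[["bound"]], sc[["bound_and_de"]],
              sc[["tier1"]], sc[["tier2"]], sc[["tier3"]],
              sc[["excluded_known"]]))
  t1 <- x$candidates[x$candidates$tier == 1L, ]
  if (nrow(t1)) {
    cat("  tier-1 candidates:",
        paste(utils::head(t1$mirna_id, 10), collapse = " "),
        if (nrow(t1) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
summary.cascade_result <- function(object, ...) {
  cat("Candidate prioritization cascade\n")
  cat("Stage counts:\n")
  print(object$stage_counts)
  cat("\nTier-1 candidates:\n")
  print(object$candidates[object$candidates$tier == 1L,
                          c("mirna_id", "genomic_class", "distance_bp",
                            "de_direction", "de_fdr")],
        row.names = FALSE)
  invisible(object)
}

#' Clinical covariate association for one feature
#'
#' Contrasts GCNIS present vs absent, stage II vs I and stage III vs I. Each
#' contrast runs [differential_expression()] over all features (so the BH
#' family is the full feature set within the contrast) and reads off the
#' focal feature. A flag is raised when the contrast FDR is below `alpha`.
#' Contrast levels with fewer than 2 samples are reported as not evaluable.
#'
#' @param norm Normalized matrix from [normalize_log2()].
#' @param meta Metadata `data.frame` with `sample_id`, `gcnis`
#'   (`present`/`absent`/`unknown`) and `stage` (`I`/`II`/`III`/`unknown`).
#' @param feature Feature id to report.
#' @param alpha FDR threshold, default 0.05.
#' @return A list (class `clinical_association`) with `flags` (subset of
#'   `c("gcnis_assoc", "stage_assoc")`) and `contrasts` (per contrast, the
#'   feature's DE row or the string `"not evaluable"`).
#' @export
clinical_association <- function(norm, meta, feature, alpha = 0.05) {
  if (!feature %in% rownames(norm))
    stop("feature not in matrix: ", feature, call. = FALSE)
  grp <- function(col, level) meta$sample_id[meta[[col]] == level]
  specs <- list(
    gcnis = list(a = grp("gcnis", "present"), b = grp("gcnis", "absent")),
    stage_II_vs_I = list(a = grp("stage", "II"), b = grp("stage", "I")),
    stage_III_vs_I = list(a = grp("stage", "III"), b = grp("stage", "I"))
  )
  contrasts <- lapply(specs, function(s) {
    if (length(s$a) < 2L || length(s$b) < 2L) return("not evaluable")
    de <- differential_expression(norm, s$a, s$b, alpha = alpha,
                                  expression_floor = -Inf)
    de[de$feature_id == feature, , drop = FALSE]
  })
  sig <- vapply(contrasts, function(d) {
    if (is.character(d)) return(FALSE)
    nrow(d) == 1L && d$fdr < alpha
  }, TRUE)
  flags <- character()
  if (sig[["gcnis"]]) flags <- c(flags, "gcnis_assoc")
  if (sig[["stage_II_vs_I"]] || sig[["stage_III_vs_I"]])
    flags <- c(flags, "stage_assoc")
  structure(list(feature = feature, flags = flags, contrasts = contrasts,
                 alpha = alpha),
            class = "clinical_association")
}

#' @export
print.clinical_association <- function(x, ...) {
  cat(sprintf("<clinical_association> %s: flags {%s}\n", x$feature,
              paste(x$flags, collapse = ", ")))
  invisible(x)
}
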