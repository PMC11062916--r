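#' Configuration for the synthetic study generator
#'
#' Defines the simulated study: a cohort of tumour samples across four
#' subtypes with a continuous driver-gene (pluripotency factor) expression
#' axis, negative-binomial miRNA counts with a planted subset whose means are
#' coupled to the driver, replicate ChIP peaks placed at controlled distances
#' upstream of planted loci, two microarray-like tumour-versus-normal
#' fold-change cohorts, and clinical covariates (GCNIS, stage) whose
#' probabilities shift with the driver axis. Every artifact is a pure
#' function of this configuration: the same config gives bit-identical
#' output.
#'
#' @param seed Integer master seed.
#' @param n_mirnas Number of simulated miRNA loci (default 200).
#' @param fraction_intronic Fraction of loci labelled intronic (default
#'   0.3).
#' @param n_planted_regulated Number of truly driver-regulated miRNAs
#'   (default 30); half induced, half repressed.
#' @param planted_log2fc Magnitude of the planted high-versus-low log2 fold
#'   change (default 2).
#' @param nb_dispersion Negative-binomial dispersion, constant across
#'   features (default 0.3).
#' @param n_samples_per_subtype Named integer vector of samples per subtype
#'   (default `c(SEM = 40, EC = 30, TERA = 10, YST = 10)`).
#' @param driver_effect Coupling multiplier from driver percentile to the
#'   planted effect; 1.5 makes the realized top-versus-bottom tertile
#'   contrast equal `planted_log2fc`.
#' @param planted_distance_range Uniform range (bp) of true binding
#'   distances for planted loci (default `c(0, 1800)`).
#' @param decoy_distance_range Uniform range (bp) of binding distances for
#'   bound-but-unregulated decoy loci (default `c(3000, 20000)`; distances
#'   past 10 kb fall outside the largest window and are unbound).
#' @param n_bound_decoys Number of decoy loci that receive a peak (default
#'   20); all other unplanted loci have no nearby peak.
#' @param replicate_jitter_bp Total per-replicate positional jitter of each
#'   peak (default 50); must stay below `peak_width_bp` so strict
#'   intersection survives.
#' @param n_chip_replicates ChIP replicates per factor (default 3).
#' @param peak_width_bp Width of simulated peaks (default 400).
#' @param cohort_noise_sd SD of log2 fold-change noise in the normal-tissue
#'   cohorts (default 0.2).
#' @param clinical_coupling List of baseline probabilities and slopes (per
#'   driver percentile) for GCNIS presence and stages II/III.
#' @param tf Transcription factor name (default `"NANOG"`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_mirnas = 200,
                       fraction_intronic = 0.3,
                       n_planted_regulated = 30,
                       planted_log2fc = 2,
                       nb_dispersion = 0.3,
                       n_samples_per_subtype = c(SEM = 40, EC = 30,
                                                 TERA = 10, YST = 10),
                       driver_effect = 1.5,
                       planted_distance_range = c(0, 1800),
                       decoy_distance_range = c(3000, 20000),
                       n_bound_decoys = 20,
                       replicate_jitter_bp = 50,
                       n_chip_replicates = 3,
                       peak_width_bp = 400,
                       cohort_noise_sd = 0.2,
                       clinical_coupling = list(gcnis_base = 0.2,
                                                gcnis_slope = 0.6,
                                                stage2_base = 0.10,
                                                stage2_slope = 0.35,
                                                stage3_base = 0.05,
                                                stage3_slope = 0.25),
                       tf = "NANOG") {
  stopifnot(n_mirnas >= 3, n_planted_regulated >= 0,
            n_planted_regulated + n_bound_decoys <= n_mirnas,
            fraction_intronic >= 0, fraction_intronic <= 1,
            nb_dispersion > 0, all(n_samples_per_subtype >= 0),
            planted_log2fc > 0, n_chip_replicates >= 1,
            replicate_jitter_bp >= 0, peak_width_bp > 0,
            cohort_noise_sd >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> seed %d: %d miRNAs (%d planted regulated, %d bound decoys), %d samples\n",
    x$seed, x$n_mirnas, x$n_planted_regulated, x$n_bound_decoys,
    sum(x$n_samples_per_subtype)))
  invisible(x)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate the synthetic miRNA locus annotation
#'
#' Non-overlapping loci on a single synthetic chromosome (`chrS`), spaced ~50
#' kb apart so that upstream windows and simulated peaks of neighbouring loci
#' never interfere; strands alternate at random.
#'
#' @param cfg A [sim_config()].
#' @return A [mirna_loci()] table.
#' @export
gen_annotation <- function(cfg) {
  with_seed(cfg$seed + 101L, {
    n <- cfg$n_mirnas
    start <- 30000 + (seq_len(n) - 1L) * 50000 +
      round(stats::runif(n, 0, 5000))
    len <- sample(80:300, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    n_intronic <- round(n * cfg$fraction_intronic)
    class <- rep("intergenic", n)
    idx <- sample.int(n, n_intronic)
    class[idx] <- "intronic"
    host <- rep(NA_character_, n)
    host[idx] <- sprintf("HOSTG%03d", seq_along(idx))
    mirna_loci(sprintf("sim-mir-%03d", seq_len(n)), "chrS", start,
               start + len, strand, class, host)
  })
}

#' Generate the planted ground truth
#'
#' Chooses which miRNAs are driver-regulated (with signed effects: half
#' induced, half repressed), which unregulated decoys carry a peak, and the
#' true binding distances. `planted_regulated` miRNAs all receive close
#' (within the planted range) binding, so the regulated set is a subset of
#' the bound set.
#'
#' @param cfg A [sim_config()].
#' @param annotation A [gen_annotation()] table.
#' @return A list of class `ground_truth` with `planted` (a `data.frame`
#'   with `mirna_id`, `role` (`regulated`/`decoy`), `sign`, `distance_bp`),
#'   `regulated_ids`, `clinical_associated`.
#' @export
gen_ground_truth <- function(cfg, annotation) {
  with_seed(cfg$seed + 202L, {
    ids <- annotation$mirna_id
    reg <- sort(sample(ids, cfg$n_planted_regulated))
    sign <- rep(c(-1, 1), length.out = length(reg))
    dec <- sort(sample(setdiff(ids, reg), cfg$n_bound_decoys))
    planted <- rbind(
      data.frame(mirna_id = reg, role = rep("regulated", length(reg)),
                 sign = sign,
                 distance_bp = round(stats::runif(length(reg),
                                                  cfg$planted_distance_range[1],
                                                  cfg$planted_distance_range[2])),
                 stringsAsFactors = FALSE),
      data.frame(mirna_id = dec, role = rep("decoy", length(dec)),
                 sign = rep(0, length(dec)),
                 distance_bp = round(stats::runif(length(dec),
                                                  cfg$decoy_distance_range[1],
                                                  cfg$decoy_distance_range[2])),
                 stringsAsFactors = FALSE)
    )
    structure(list(planted = planted, regulated_ids = reg,
                   clinical_associated = reg),
              class = "ground_truth")
  })
}

#' Generate replicate ChIP peak sets
#'
#' For every planted (regulated or decoy) locus a peak of width
#' `peak_width_bp` is placed at the drawn distance upstream of the locus 5'
#' end and shifted by an independent jitter per replicate, small enough that
#' strict intersection across replicates always survives. A sprinkling of
#' background peaks far from any locus is added to every replicate. The
#' realized consensus distances (after jitter) are recorded back onto the
#' returned truth.
#'
#' @param cfg A [sim_config()].
#' @param annotation A [gen_annotation()] table.
#' @param truth A [gen_ground_truth()] object.
#' @return A list with `peak_sets` (a list of [peak_set()], one per
#'   replicate) and `truth` (the input truth with `consensus_distance_bp`
#'   and `bound` columns added to `$planted`).
#' @export
gen_chip_replicates <- function(cfg, annotation, truth) {
  if (cfg$replicate_jitter_bp >= cfg$peak_width_bp)
    stop("replicate_jitter_bp must be smaller than peak_width_bp, ",
         "or strict-intersection consensus would vanish", call. = FALSE)
  with_seed(cfg$seed + 303L, {
    pl <- truth$planted
    i <- match(pl$mirna_id, annotation$mirna_id)
    plus <- annotation$strand[i] == "+"
    tss <- ifelse(plus, annotation$start[i], annotation$end[i])
    w <- cfg$peak_width_bp
    base_start <- ifelse(plus, tss - pl$distance_bp - w, tss + pl$distance_bp)
    j2 <- floor(cfg$replicate_jitter_bp / 2)
    deltas <- matrix(
      if (j2 > 0) sample(seq(-j2, j2), nrow(pl) * cfg$n_chip_replicates,
                         replace = TRUE) else 0L,
      nrow = nrow(pl), ncol = cfg$n_chip_replicates
    )
    # background peaks in inter-locus gaps, identical concept per replicate
    bg_start <- 5000 + seq(0, by = 500000, length.out = max(1, cfg$n_mirnas %/% 10))
    reps <- lapply(seq_len(cfg$n_chip_replicates), function(r) {
      st <- pmax(0, base_start + deltas[, r])
      gr <- genomic_intervals(
        chrom = rep("chrS", nrow(pl) + length(bg_start)),
        start = c(st, bg_start),
        end = c(st + w, bg_start + 300),
        strand = ".",
        name = c(if (nrow(pl)) paste0("peak_", pl$mirna_id),
                 sprintf("bg%02d", seq_along(bg_start)))
      )
      peak_set(cfg$tf, paste0("rep", r), BiocGenerics::sort(gr))
    })
    # realized consensus peak after jitter: [base_start + max(delta),
    # base_start + w + min(delta)); distance measured from its TSS-near edge
    dmax <- apply(deltas, 1, max)
    dmin <- apply(deltas, 1, min)
    cons_dist <- ifelse(plus, pl$distance_bp - dmin, pl$distance_bp + dmax)
    cons_dist <- pmax(0, cons_dist)
    pl$consensus_distance_bp <- cons_dist
    pl$bound <- cons_dist < 10000
    truth$planted <- pl
    list(peak_sets = reps, truth = truth)
  })
}

clamp01 <- function(p) pmin(1, pmax(0, p))

#' Generate tumour counts, driver expression and clinical metadata
#'
#' Driver expression is drawn per sample around subtype-level means (SEM and
#' EC high, TERA and YST low) on a log2 normalized-counts scale. Counts are
#' negative-binomial; the means of planted regulated miRNAs are multiplied
#' by `2^(sign * driver_effect * planted_log2fc * (u - 1/2))` where `u` is
#' the sample's driver percentile. GCNIS and stage probabilities shift with
#' the same percentile, which is what couples clinical covariates to the
#' planted candidates.
#'
#' @param cfg A [sim_config()].
#' @param annotation A [gen_annotation()] table.
#' @param truth A [gen_ground_truth()] object.
#' @return A list with `counts` (matrix miRNAs x samples), `driver` (named
#'   numeric vector, log2 scale), `metadata` (`sample_id`, `subtype`,
#'   `gcnis`, `stage`).
#' @export
gen_tumour_counts <- function(cfg, annotation, truth) {
  with_seed(cfg$seed + 404L, {
    nss <- cfg$n_samples_per_subtype
    subtype <- rep(names(nss), nss)
    n <- length(subtype)
    sample_id <- sprintf("S%03d", seq_len(n))
    drv_mean <- c(SEM = 13.2, EC = 12.9, TERA = 10.8, YST = 10.5,
                  mixed = 11.8)[subtype]
    driver <- stats::setNames(stats::rnorm(n, drv_mean, 0.8), sample_id)
    u <- (rank(driver, ties.method = "first") - 0.5) / n
    ids <- annotation$mirna_id
    base <- 2^stats::runif(length(ids), 4, 9)
    sign <- stats::setNames(rep(0, length(ids)), ids)
    reg <- truth$planted[truth$planted$role == "regulated", ]
    sign[reg$mirna_id] <- reg$sign
    lfc <- outer(sign, cfg$driver_effect * cfg$planted_log2fc * (u - 0.5))
    mu <- base * 2^lfc
    counts <- matrix(
      stats::rnbinom(length(mu), size = 1 / cfg$nb_dispersion, mu = mu),
      nrow = length(ids), dimnames = list(ids, sample_id)
    )
    cc <- cfg$clinical_coupling
    gcnis <- ifelse(stats::runif(n) < clamp01(cc$gcnis_base +
                                                cc$gcnis_slope * u),
                    "present", "absent")
    p3 <- clamp01(cc$stage3_base + cc$stage3_slope * u)
    p2 <- clamp01(cc$stage2_base + cc$stage2_slope * u)
    r <- stats::runif(n)
    stage <- ifelse(r < p3, "III", ifelse(r < p3 + p2, "II", "I"))
    metadata <- data.frame(sample_id = sample_id, subtype = subtype,
                           gcnis = gcnis, stage = stage,
                           stringsAsFactors = FALSE)
    list(counts = counts, driver = driver, metadata = metadata)
  })
}

#' Generate two tumour-versus-normal fold-change cohorts
#'
#' Planted regulated miRNAs receive log2 fold changes of
#' `sign * planted_log2fc` plus Gaussian noise, so they exceed the 1.5-fold
#' rule in the truth direction in almost all draws; all other miRNAs sit
#' near a ratio of 1.
#'
#' @param cfg A [sim_config()].
#' @param annotation A [gen_annotation()] table.
#' @param truth A [gen_ground_truth()] object.
#' @return A list of two fold-change `data.frame`s (`mirna_id`,
#'   `fold_change`, `cohort_id`).
#' @export
gen_normal_cohorts <- function(cfg, annotation, truth) {
  with_seed(cfg$seed + 505L, {
    ids <- annotation$mirna_id
    sign <- stats::setNames(rep(0, length(ids)), ids)
    reg <- truth$planted[truth$planted$role == "regulated", ]
    sign[reg$mirna_id] <- reg$sign
    one <- function(cohort_id) {
      l2 <- sign * cfg$planted_log2fc +
        stats::rnorm(length(ids), 0, cfg$cohort_noise_sd)
      data.frame(mirna_id = ids, fold_change = 2^l2,
                 cohort_id = cohort_id, stringsAsFactors = FALSE)
    }
    list(one("cohortA"), one("cohortB"))
  })
}

#' Simulate a complete synthetic study
#'
#' Runs all generators and bundles their output with the ground truth.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_study`: `annotation`, `truth`, `chip` (list
#'   of replicate [peak_set()]s), `counts`, `driver`, `metadata`, `cohorts`,
#'   `config`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  annotation <- gen_annotation(cfg)
  truth <- gen_ground_truth(cfg, annotation)
  chip <- gen_chip_replicates(cfg, annotation, truth)
  truth <- chip$truth
  expr <- gen_tumour_counts(cfg, annotation, truth)
  cohorts <- gen_normal_cohorts(cfg, annotation, truth)
  structure(list(annotation = annotation, truth = truth,
                 chip = chip$peak_sets, counts = expr$counts,
                 driver = expr$driver, metadata = expr$metadata,
                 cohorts = cohorts, config = cfg),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "<sim_study> %d miRNAs x %d samples, %d ChIP replicates, %d cohorts (seed %d)\n",
    nrow(x$annotation), ncol(x$counts), length(x$chip), length(x$cohorts),
    x$config$seed))
  invisible(x)
}

#' Write a simulated study to plain-text files
#'
#' Emits the full input bundle: locus annotation TSV, one BED per ChIP
#' replicate, counts/metadata/driver TSVs, one fold-change TSV per cohort, a
#' ground-truth JSON and a config snapshot JSON.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_tsv(as.data.frame(study$annotation), p("annotation.tsv"))
  for (ps in study$chip)
    write_bed(ps$peaks, p(sprintf("chip_%s_%s.bed", ps$factor,
                                  ps$replicate_id)))
  write_counts(study$counts, p("counts.tsv"), id_col = "mirna_id")
  write_tsv(study$metadata, p("metadata.tsv"))
  write_tsv(data.frame(sample_id = names(study$driver),
                       driver_log2 = unname(study$driver)),
            p("driver.tsv"))
  for (co in study$cohorts)
    write_tsv(co[c("mirna_id", "fold_change")],
              p(sprintf("foldchange_%s.tsv", co$cohort_id[1])))
  jsonlite::write_json(
    list(planted = study$truth$planted,
         regulated_ids = study$truth$regulated_ids,
         clinical_associated = study$truth$clinical_associated),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  cfg <- study$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulated study bundle back from disk
#'
#' Inverse of [write_simulation()] (the ground truth is reloaded too).
#'
#' @param dir Directory written by [write_simulation()].
#' @return A list of class `sim_study`.
#' @export
read_simulation <- function(dir) {
  p <- function(f) file.path(dir, f)
  cfg <- jsonlite::read_json(p("config.json"), simplifyVector = TRUE)
  cfg$n_samples_per_subtype <- unlist(cfg$n_samples_per_subtype)
  cfg <- do.call(sim_config, cfg)
  annotation <- read_mirna_annotation(p("annotation.tsv"))
  beds <- sort(list.files(dir, pattern = "^chip_.*\\.bed$"))
  chip <- lapply(beds, function(f) {
    parts <- strsplit(sub("\\.bed$", "", f), "_")[[1]]
    peak_set(parts[2], parts[3], read_bed(p(f)))
  })
  counts <- read_counts(p("counts.tsv"))
  metadata <- read_sample_metadata(p("metadata.tsv"))
  drv <- utils::read.delim(p("driver.tsv"), stringsAsFactors = FALSE)
  driver <- stats::setNames(drv$driver_log2, drv$sample_id)
  fcs <- sort(list.files(dir, pattern = "^foldchange_.*\\.tsv$"))
  cohorts <- lapply(fcs, function(f)
    read_fold_changes(p(f), sub("^foldchange_(.*)\\.tsv$", "\\1", f)))
  tr <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  truth <- structure(list(planted = tr$planted,
                          regulated_ids = tr$regulated_ids,
                          clinical_associated = tr$clinical_associated),
                     class = "ground_truth")
  structure(list(annotation = annotation, truth = truth, chip = chip,
                 counts = counts, driver = driver, metadata = metadata,
                 cohorts = cohorts, config = cfg),
            class = "sim_study")
}
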