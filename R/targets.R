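#' Consensus of target predictions across algorithms
#'
#' @param sets Named list of predicted gene-id sets, one per algorithm.
#' @param min_votes Minimum number of algorithms that must agree (between 1
#'   and `length(sets)`); default 2.
#' @return A `data.frame` with `gene_id` and `votes`, restricted to genes
#'   with `votes >= min_votes`, sorted by descending votes then gene id.
#' @export
target_consensus <- function(sets, min_votes = 2) {
  if (min_votes < 1 || min_votes > length(sets))
    stop("min_votes must lie between 1 and the number of algorithms (",
         length(sets), ")", call. = FALSE)
  sets <- lapply(sets, unique)
  genes <- unique(unlist(sets, use.names = FALSE))
  if (any(!nzchar(genes)))
    stop("empty gene id in a prediction set", call. = FALSE)
  votes <- rowSums(vapply(sets, function(s) genes %in% s,
                          logical(length(genes))))
  out <- data.frame(gene_id = genes, votes = as.integer(votes),
                    stringsAsFactors = FALSE)
  out <- out[out$votes >= min_votes, , drop = FALSE]
  out <- out[order(-out$votes, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Three-way overlap of downregulated genes, predicted targets and a
#' signature
#'
#' The triple intersection is the set of direct targets inside the
#' signature.
#'
#' @param downregulated,predicted_targets,signature Character gene-id sets
#'   (already harmonized).
#' @return A [set_overlap()] over the three sets plus a `direct_targets`
#'   element (the triple intersection).
#' @export
signature_overlap <- function(downregulated, predicted_targets, signature) {
  ov <- set_overlap(list(downregulated = downregulated,
                         predicted = predicted_targets,
                         signature = signature))
  ov$direct_targets <-
    sort(intersect(intersect(unique(downregulated),
                             unique(predicted_targets)),
                   unique(signature)))
  ov
}

parse_band <- function(band) {
  ok <- grepl("^([0-9]+|[XY])[pq][0-9.]*$", band)
  if (any(!ok))
    stop("unparseable cytoband label: ", band[!ok][1], call. = FALSE)
  invisible(band)
}

#' Filter genes by cytoband prefix
#'
#' @param genes Character vector of gene ids.
#' @param map Named character vector gene id -> band label (e.g.
#'   `"12p13.31"`).
#' @param band_prefix Chromosome + arm (+ optional sub-band) prefix, default
#'   `"12p"`.
#' @return A list with `genes` (those whose band starts with the prefix) and
#'   `unmapped` (genes absent from the map, reported rather than dropped).
#' @export
cytoband_filter <- function(genes, map, band_prefix = "12p") {
  if (!grepl("^([0-9]+|[XY])[pq]", band_prefix))
    stop("band_prefix must start with a chromosome and arm, e.g. '12p'",
         call. = FALSE)
  parse_band(unname(map))
  genes <- unique(genes)
  unmapped <- genes[!genes %in% names(map)]
  mapped <- setdiff(genes, unmapped)
  hit <- mapped[startsWith(unname(map[mapped]), band_prefix)]
  list(genes = sort(hit), unmapped = sort(unmapped),
       band_prefix = band_prefix)
}

# average technical replicates: one Ct per (sample, gene)
ct_by_sample_gene <- function(ct) {
  agg <- stats::aggregate(ct$ct, list(sample = ct$sample, gene = ct$gene),
                          mean)
  names(agg)[3] <- "ct"
  agg
}

#' Rank candidate reference genes by Ct stability
#'
#' Technical replicates are averaged per sample first; candidates are ranked
#' by ascending standard deviation of Ct across samples (the core descriptor
#' of reference-gene stability), with ties broken by coefficient of
#' variation, then name. Candidates measured in fewer than half of the
#' samples are excluded with a reason.
#'
#' @param ct Long-format Ct table (`sample`, `gene`, `replicate`, `ct`).
#' @param candidate_refs Character vector of candidate reference genes.
#' @return A list with `ranking` (`data.frame`: `gene`, `sd`, `cv`,
#'   `n_samples`, `rank`) and `excluded` (`data.frame`: `gene`, `reason`).
#' @export
reference_stability <- function(ct, candidate_refs) {
  agg <- ct_by_sample_gene(ct)
  n_total <- length(unique(agg$sample))
  rows <- list(); excl <- list()
  for (g in candidate_refs) {
    v <- agg$ct[agg$gene == g]
    if (length(v) < n_total / 2) {
      excl[[g]] <- data.frame(gene = g,
                              reason = sprintf("measured in %d/%d samples",
                                               length(v), n_total),
                              stringsAsFactors = FALSE)
      next
    }
    if (length(v) < 2L) {
      excl[[g]] <- data.frame(gene = g, reason = "fewer than 2 samples",
                              stringsAsFactors = FALSE)
      next
    }
    rows[[g]] <- data.frame(gene = g, sd = stats::sd(v),
                            cv = stats::sd(v) / mean(v),
                            n_samples = length(v), stringsAsFactors = FALSE)
  }
  ranking <- do.call(rbind, rows)
  if (!is.null(ranking)) {
    ranking <- ranking[order(ranking$sd, ranking$cv, ranking$gene), ,
                       drop = FALSE]
    ranking$rank <- seq_len(nrow(ranking))
    rownames(ranking) <- NULL
  }
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(gene = character(), reason = character(),
               stringsAsFactors = FALSE)
  rownames(excluded) <- NULL
  list(ranking = ranking, excluded = excluded)
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Per sample (replicates averaged), `dCt = Ct_target - Ct_reference`; then
#' `ddCt = dCt - mean(dCt over the control group)` and the fold change is
#' `2^(-ddCt)` (amplification efficiency fixed at 2).
#'
#' @param ct Long-format Ct table.
#' @param target,reference Gene ids; both must be measured in every involved
#'   sample.
#' @param control_group,treated_group Character vectors of sample ids.
#' @return A list (class `ddct_result`) with `per_sample` (`data.frame`:
#'   `sample`, `dct`, `ddct`, `fold` for the treated samples), `mean_fold`,
#'   `sd_fold` and `control_mean_dct`.
#' @export
ddct_fold_change <- function(ct, target, reference, control_group,
                             treated_group) {
  if (length(control_group) == 0L)
    stop("control group must not be empty", call. = FALSE)
  agg <- ct_by_sample_gene(ct)
  involved <- unique(c(control_group, treated_group))
  get_ct <- function(gene) {
    v <- agg$ct[agg$gene == gene][match(involved,
                                        agg$sample[agg$gene == gene])]
    if (anyNA(v))
      stop(gene, " missing in sample(s): ",
           paste(involved[is.na(v)], collapse = ", "), call. = FALSE)
    stats::setNames(v, involved)
  }
  dct <- get_ct(target) - get_ct(reference)
  ctrl_mean <- mean(dct[control_group])
  ddct <- dct[treated_group] - ctrl_mean
  fold <- 2^(-ddct)
  per_sample <- data.frame(sample = treated_group,
                           dct = unname(dct[treated_group]),
                           ddct = unname(ddct), fold = unname(fold),
                           stringsAsFactors = FALSE)
  structure(list(per_sample = per_sample, mean_fold = mean(fold),
                 sd_fold = stats::sd(fold), control_mean_dct = ctrl_mean,
                 target = target, reference = reference),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("<ddct_result> %s vs %s: fold %.3g +/- %.3g (n = %d)\n",
              x$target, x$reference, x$mean_fold,
              ifelse(is.na(x$sd_fold), 0, x$sd_fold),
              nrow(x$per_sample)))
  invisible(x)
}
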