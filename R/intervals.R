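#' Construct a validated set of genomic intervals
#'
#' Intervals are held as a [GenomicRanges::GRanges] using the BED convention
#' internally: 0-based starts, half-open ends (`[start, end)`). The `start`
#' argument here is therefore 0-based and `end` is exclusive; a one-base
#' interval covering the first base of a chromosome is `start = 0, end = 1`.
#'
#' @param chrom Character vector of chromosome names (matched verbatim; no
#'   "chr" aliasing is applied).
#' @param start Integer vector, 0-based inclusive starts (bp).
#' @param end Integer vector, exclusive ends (bp); must satisfy `end > start`.
#' @param strand Strand per interval: `"+"`, `"-"` or `"."` (unstranded).
#' @param name Optional identifier per interval.
#' @return A `GRanges` object. Note that `GRanges` prints 1-based inclusive
#'   coordinates; [gi_start0()] and [gi_end0()] recover the 0-based half-open
#'   view.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", name = NULL) {
  n <- length(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  strand <- rep_len(as.character(strand), n)
  if (is.null(name)) name <- rep_len("", n)
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | end <= start)
  if (length(bad)) {
    id <- if (nzchar(name[bad[1]])) name[bad[1]] else paste0("record ", bad[1])
    stop("invalid interval (need 0 <= start < end) at ", id, ": ",
         chrom[bad[1]], ":[", start[bad[1]], ",", end[bad[1]], ")",
         call. = FALSE)
  }
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand
  )
  gr$name <- name
  gr
}

#' 0-based half-open coordinates of a GRanges
#'
#' @param gr A `GRanges`.
#' @return Numeric vector of 0-based starts (`gi_start0`) or exclusive ends
#'   (`gi_end0`).
#' @export
gi_start0 <- function(gr) BiocGenerics::start(gr) - 1

#' @rdname gi_start0
#' @export
gi_end0 <- function(gr) BiocGenerics::end(gr)

#' Length of each interval in base pairs
#'
#' For half-open intervals the length is simply `end - start`.
#'
#' @param gr A `GRanges`.
#' @return Integer vector of widths (bp).
#' @export
interval_length <- function(gr) {
  BiocGenerics::width(gr)
}

# Make two GRanges share a seqlevel universe so set ops do not warn.
align_seqlevels <- function(a, b) {
  lev <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lev
  GenomeInfoDb::seqlevels(b) <- lev
  list(a = a, b = b)
}

#' Per-base intersection of two interval collections
#'
#' Returns the exact set of bases present in both inputs, as sorted, merged,
#' maximal intervals per chromosome. Strand is ignored: ChIP peaks are
#' unstranded evidence.
#'
#' @param a,b `GRanges` interval collections (any order, any overlap
#'   structure).
#' @return A sorted, reduced `GRanges`.
#' @export
intersect_interval_sets <- function(a, b) {
  stopifnot(methods::is(a, "GRanges"), methods::is(b, "GRanges"))
  al <- align_seqlevels(a, b)
  out <- GenomicRanges::intersect(al$a, al$b, ignore.strand = TRUE)
  out$name <- rep_len("", length(out))
  out
}

#' A replicate peak set for one transcription factor
#'
#' @param factor TF name (e.g. `"NANOG"`).
#' @param replicate_id Replicate label.
#' @param peaks `GRanges` of peak calls; zero-length peaks are impossible by
#'   construction of [genomic_intervals()].
#' @return An object of class `peak_set`.
#' @export
peak_set <- function(factor, replicate_id, peaks) {
  stopifnot(is.character(factor), length(factor) == 1L,
            methods::is(peaks, "GRanges"))
  structure(list(factor = factor, replicate_id = as.character(replicate_id),
                 peaks = peaks),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %s replicate %s: %d peaks\n",
              x$factor, x$replicate_id, length(x$peaks)))
  invisible(x)
}

#' Consensus peaks present in every replicate
#'
#' Strict intersection: a base belongs to the consensus iff it is covered by a
#' peak in every replicate. A single replicate returns its own sorted, merged
#' peaks.
#'
#' @param replicates A list of [peak_set()] objects or bare `GRanges`.
#' @return A sorted, reduced `GRanges` of consensus regions.
#' @export
consensus_across_replicates <- function(replicates) {
  if (length(replicates) == 0L)
    stop("need at least one replicate peak set", call. = FALSE)
  grs <- lapply(replicates, function(r) {
    if (inherits(r, "peak_set")) r$peaks else r
  })
  out <- GenomicRanges::reduce(BiocGenerics::sort(grs[[1]]),
                               ignore.strand = TRUE)
  if (length(grs) > 1L) {
    for (g in grs[-1]) out <- intersect_interval_sets(out, g)
  }
  out$name <- rep_len("", length(out))
  out
}

#' Build a miRNA locus annotation table
#'
#' @param mirna_id Canonical miRNA identifiers (unique).
#' @param chrom,start,end,strand Locus coordinates, 0-based half-open;
#'   `strand` must be `"+"` or `"-"` for every locus that will enter binding
#'   assignment (upstream is undefined otherwise).
#' @param genomic_class `"intergenic"` or `"intronic"` per locus.
#' @param host_gene Host gene for intronic loci (`NA` for intergenic).
#' @return A `data.frame` with class `mirna_loci`.
#' @export
mirna_loci <- function(mirna_id, chrom, start, end, strand, genomic_class,
                       host_gene = NA_character_) {
  if (anyDuplicated(mirna_id))
    stop("duplicated mirna_id in locus annotation", call. = FALSE)
  bad <- which(!(genomic_class %in% c("intergenic", "intronic")))
  if (length(bad))
    stop("genomic_class must be 'intergenic' or 'intronic' (locus ",
         mirna_id[bad[1]], ")", call. = FALSE)
  # construct once to validate coordinates
  genomic_intervals(chrom, start, end, strand, mirna_id)
  out <- data.frame(
    mirna_id = as.character(mirna_id),
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = as.character(strand),
    genomic_class = as.character(genomic_class),
    host_gene = rep_len(as.character(host_gene), length(mirna_id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("mirna_loci", "data.frame")
  out
}

loci_granges <- function(loci) {
  genomic_intervals(loci$chrom, loci$start, loci$end, loci$strand,
                    loci$mirna_id)
}

#' Strand-aware upstream window of a locus
#'
#' The window abuts the locus 5' end without overlapping it: for a plus-strand
#' locus `[s, e)` and window size `k` it is `[max(0, s - k), s)`; for a
#' minus-strand locus it is `[e, e + k)`. The window is shorter than `k` only
#' when clipped at the chromosome origin.
#'
#' @param loci A [mirna_loci()] table (or any data.frame with `chrom`,
#'   `start`, `end`, `strand`, `mirna_id` columns, 0-based half-open).
#' @param k Window size in bp (> 0).
#' @return A `GRanges` of windows, named by `mirna_id`.
#' @export
upstream_window <- function(loci, k) {
  stopifnot(k > 0)
  if (any(!loci$strand %in% c("+", "-")))
    stop("upstream window undefined for unstranded locus: ",
         loci$mirna_id[which(!loci$strand %in% c("+", "-"))[1]],
         call. = FALSE)
  plus <- loci$strand == "+"
  ws <- ifelse(plus, pmax(0, loci$start - k), loci$end)
  we <- ifelse(plus, loci$start, loci$end + k)
  keep <- we > ws  # a plus-strand locus starting at 0 has an empty window
  genomic_intervals(loci$chrom[keep], ws[keep], we[keep], ".",
                    loci$mirna_id[keep])
}

#' Assign consensus-peak binding to miRNA loci at graded upstream windows
#'
#' For every locus, `bound` means at least `min_overlap_bp` of a consensus
#' peak falls inside the largest upstream window (default 10 kb);
#' `smallest_window_kb` is the smallest of the graded windows with such an
#' overlap, and `distance_bp` is the gap from the nearest qualifying peak edge
#' to the locus 5' end (0 when a peak covers the 5' end).
#'
#' @param loci A [mirna_loci()] table.
#' @param peaks `GRanges` of consensus peaks.
#' @param windows_kb Graded window sizes in kb, ascending (default
#'   `c(1, 2, 5, 10)`).
#' @param factor TF name recorded on each assignment.
#' @param min_overlap_bp Minimum peak/window overlap (bp) to count as bound;
#'   default 1.
#' @return A `data.frame` (class `binding_assignment`) with columns
#'   `mirna_id`, `factor`, `bound`, `smallest_window_kb` (`NA` when unbound),
#'   `distance_bp` (`NA` when unbound), plus `genomic_class` carried over from
#'   the annotation.
#' @export
assign_binding <- function(loci, peaks, windows_kb = c(1, 2, 5, 10),
                           factor = "TF", min_overlap_bp = 1) {
  stopifnot(length(windows_kb) >= 1, !is.unsorted(windows_kb),
            min_overlap_bp >= 1)
  if (any(!loci$strand %in% c("+", "-")))
    stop("locus missing strand: ",
         loci$mirna_id[which(!loci$strand %in% c("+", "-"))[1]],
         call. = FALSE)
  n <- nrow(loci)
  smallest <- rep(NA_real_, n)
  distance <- rep(NA_real_, n)
  maxk <- max(windows_kb)
  # 5' end coordinate (0-based): start for +, end for - (the exclusive end is
  # the boundary just past the 5'-most base, which is where upstream begins)
  tss <- ifelse(loci$strand == "+", loci$start, loci$end)
  for (k in rev(windows_kb)) {
    win <- upstream_window(loci, k * 1000)
    al <- align_seqlevels(win, peaks)
    ov <- GenomicRanges::findOverlaps(al$a, al$b,
                                      minoverlap = min_overlap_bp,
                                      ignore.strand = TRUE)
    if (length(ov)) {
      idx <- match(al$a$name[S4Vectors::queryHits(ov)], loci$mirna_id)
      smallest[idx] <- k
      if (k == maxk) {
        ps <- gi_start0(al$b)[S4Vectors::subjectHits(ov)]
        pe <- gi_end0(al$b)[S4Vectors::subjectHits(ov)]
        t <- tss[idx]
        gap <- ifelse(loci$strand[idx] == "+",
                      pmax(0, t - pe), pmax(0, ps - t))
        distance[idx] <- NA
        agg <- tapply(gap, idx, min)
        distance[as.integer(names(agg))] <- as.numeric(agg)
      }
    }
  }
  out <- data.frame(
    mirna_id = loci$mirna_id,
    factor = factor,
    bound = !is.na(smallest),
    smallest_window_kb = smallest,
    distance_bp = distance,
    genomic_class = loci$genomic_class,
    stringsAsFactors = FALSE
  )
  class(out) <- c("binding_assignment", "data.frame")
  out
}
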