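#' Harmonize miRNA names against an alias table
#'
#' Raw names with an entry in the alias table are replaced by their canonical
#' id; names that already are canonical ids map to themselves; anything else
#' is left unchanged and reported as unmapped (never silently dropped). The
#' mapping is idempotent.
#'
#' @param names Character vector of raw miRNA names.
#' @param aliases Named character vector from [read_alias_table()] (names =
#'   raw, values = canonical).
#' @return A list with `ids` (same length as `names`) and `unmapped` (the
#'   distinct input names with no alias entry).
#' @export
harmonize_names <- function(names, aliases) {
  if (length(aliases)) {
    # a canonical id that is itself remapped elsewhere breaks idempotence
    clash <- intersect(names(aliases), unname(aliases))
    clash <- clash[aliases[clash] != clash]
    if (length(clash))
      stop("alias table remaps canonical id(s): ",
           paste(clash, collapse = ", "), call. = FALSE)
  }
  hit <- names %in% names(aliases)
  canonical <- names %in% unname(aliases)
  ids <- names
  ids[hit] <- unname(aliases[names[hit]])
  list(ids = ids, unmapped = unique(names[!hit & !canonical]))
}

#' Direction calls from a tumour-versus-normal fold-change table
#'
#' Keeps miRNAs with a fold change at least `threshold` (direction `up`) or
#' at most `1/threshold` (direction `down`) on the linear ratio scale.
#'
#' @param fc_table `data.frame` with `mirna_id`, `fold_change` (and
#'   optionally `cohort_id`) as from [read_fold_changes()].
#' @param threshold Minimum fold change (> 1), default 1.5.
#' @return A `data.frame` with `mirna_id`, `fold_change`, `direction`,
#'   `cohort_id`.
#' @export
fold_change_filter <- function(fc_table, threshold = 1.5) {
  stopifnot(threshold > 1)
  fc <- fc_table$fold_change
  if (any(!is.finite(fc) | fc <= 0))
    stop("fold changes must be positive: ",
         fc_table$mirna_id[which(!is.finite(fc) | fc <= 0)[1]],
         call. = FALSE)
  keep <- fc >= threshold | fc <= 1 / threshold
  out <- fc_table[keep, , drop = FALSE]
  out$direction <- ifelse(out$fold_change >= threshold, "up", "down")
  if (is.null(out$cohort_id)) out$cohort_id <- "cohort"
  rownames(out) <- NULL
  out[c("mirna_id", "fold_change", "direction", "cohort_id")]
}

#' Consolidate per-cohort direction calls into a unified list
#'
#' The union over cohorts, recording which cohorts support each miRNA.
#' miRNAs called `up` in one cohort and `down` in another are flagged
#' `discordant` (and are excluded from direction-consistency checks, but kept
#' in the table for audit).
#'
#' @param calls A list of direction-call `data.frame`s from
#'   [fold_change_filter()].
#' @return A `data.frame` with `mirna_id`, `direction` (`NA` when
#'   discordant), `n_cohorts`, `cohorts` (comma-separated), `discordant`.
#' @export
consolidate_cohorts <- function(calls) {
  all <- do.call(rbind, calls)
  if (is.null(all) || nrow(all) == 0L)
    return(data.frame(mirna_id = character(), direction = character(),
                      n_cohorts = integer(), cohorts = character(),
                      discordant = logical(), stringsAsFactors = FALSE))
  sp <- split(all, all$mirna_id)
  rows <- lapply(sp, function(d) {
    dirs <- unique(d$direction)
    disc <- length(dirs) > 1L
    data.frame(mirna_id = d$mirna_id[1],
               direction = if (disc) NA_character_ else dirs,
               n_cohorts = length(unique(d$cohort_id)),
               cohorts = paste(sort(unique(d$cohort_id)), collapse = ","),
               discordant = disc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$mirna_id), , drop = FALSE]
}

#' Exact Venn region memberships of 2-4 named sets
#'
#' @param sets Named list of 2-4 character vectors.
#' @param allow_large Permit more than 4 sets (region table only; there is no
#'   sensible diagram beyond 4).
#' @return A list (class `set_overlap`) with `regions` (named list of member
#'   vectors; region names are `+`-joined set names), `sizes` (named integer
#'   vector over the same regions) and `union_size`.
#' @export
set_overlap <- function(sets, allow_large = FALSE) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named", call. = FALSE)
  if (length(sets) < 2L)
    stop("need at least 2 sets", call. = FALSE)
  if (length(sets) > 4L && !allow_large)
    stop("more than 4 sets cannot be drawn; pass allow_large = TRUE for ",
         "the region table", call. = FALSE)
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "+"))
  regions <- split(universe, key)
  sizes <- vapply(regions, length, 0L)
  structure(list(regions = regions, sizes = sizes,
                 union_size = length(universe), set_names = names(sets)),
            class = "set_overlap")
}

#' @export
print.set_overlap <- function(x, ...) {
  cat("<set_overlap>", length(x$set_names), "sets, union",
      x$union_size, "\n")
  for (r in names(x$sizes)) cat(sprintf("  %-30s %d\n", r, x$sizes[[r]]))
  invisible(x)
}

#' Shared fraction of the smaller of two sets
#'
#' Convenience for reporting two-set overlaps as "percentage of the smaller
#' set shared", rounded to the nearest integer percent.
#'
#' @param a,b Character vectors.
#' @return Integer percentage.
#' @export
shared_percent_of_smaller <- function(a, b) {
  a <- unique(a); b <- unique(b)
  round(100 * length(intersect(a, b)) / min(length(a), length(b)))
}

#' Cross-cohort direction consistency
#'
#' A tumour-strata DE direction is confirmed when the miRNA is present in the
#' unified cohort list, is not discordant across cohorts, and its
#' tumour-versus-normal direction matches the tumour call.
#'
#' @param mirna_id Character vector of miRNA ids.
#' @param tumour_direction Parallel vector of tumour-contrast directions
#'   (`"up"`/`"down"`).
#' @param unified Unified cohort table from [consolidate_cohorts()].
#' @return Logical vector.
#' @export
direction_consistency <- function(mirna_id, tumour_direction, unified) {
  i <- match(mirna_id, unified$mirna_id)
  ok <- rep(FALSE, length(mirna_id))
  hit <- which(!is.na(i))
  if (length(hit)) {
    j <- i[hit]
    ok[hit] <- !unified$discordant[j] & !is.na(unified$direction[j]) &
      unified$direction[j] == tumour_direction[hit]
  }
  ok
}
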