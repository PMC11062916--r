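#' Read a BED3/BED6 file
#'
#' Tab-separated, no header. Column 4 is taken as the record name and column 6
#' as the strand when present. Files declared 1-based inclusive (some
#' annotation exports) are converted to the internal 0-based half-open
#' convention on read.
#'
#' @param path File path.
#' @param basis Coordinate basis of the file: `"0-based"` (BED standard,
#'   default) or `"1-based"` (inclusive starts are shifted down by one).
#' @return A `GRanges`.
#' @export
read_bed <- function(path, basis = c("0-based", "1-based")) {
  basis <- match.arg(basis)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(genomic_intervals(character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1], " in ", path,
         ": fewer than 3 columns", call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1], " in ",
         path, ": non-numeric coordinates", call. = FALSE)
  if (basis == "1-based") start <- start - 1
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), "")
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))], "."), ".")
  strand[!strand %in% c("+", "-")] <- "."
  bad <- which(end <= start)
  if (length(bad))
    stop("malformed BED line ", bad[1], " in ", path,
         ": end <= start after conversion", call. = FALSE)
  genomic_intervals(chrom, start, end, strand, name)
}

#' Write intervals as BED
#'
#' Writes BED6 when any record carries a name or strand, BED3 otherwise.
#' Coordinates are written as plain integers (never scientific notation) and
#' every record is newline-terminated, so write-then-read is the identity.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  s <- format(gi_start0(gr), scientific = FALSE, trim = TRUE)
  e <- format(gi_end0(gr), scientific = FALSE, trim = TRUE)
  name <- if (!is.null(gr$name)) gr$name else rep("", length(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  if (any(nzchar(name)) || any(strand != ".")) {
    name[!nzchar(name)] <- "."
    lines <- paste(chrom, s, e, name, 0L, strand, sep = "\t")
  } else {
    lines <- paste(chrom, s, e, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a miRNA locus annotation table
#'
#' Expected TSV header:
#' `mirna_id  chrom  start  end  strand  genomic_class  host_gene`.
#'
#' @param path File path.
#' @param basis Coordinate basis of the table: `"0-based"` half-open
#'   (default) or `"1-based"` inclusive.
#' @return A [mirna_loci()] table (0-based half-open).
#' @export
read_mirna_annotation <- function(path, basis = c("0-based", "1-based")) {
  basis <- match.arg(basis)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "chrom", "start", "end", "strand", "genomic_class")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation table ", path, " missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(df$host_gene)) df$host_gene <- NA_character_
  start <- if (basis == "1-based") df$start - 1 else df$start
  mirna_loci(df$mirna_id, df$chrom, start, df$end, df$strand,
             df$genomic_class, df$host_gene)
}

#' Read a count matrix
#'
#' Features as rows; first column feature ids, header row of sample ids.
#'
#' @param path TSV/CSV path (delimiter sniffed from the extension: `.csv`
#'   uses commas, anything else tabs).
#' @return Numeric matrix, features x samples.
#' @export
read_counts <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a count matrix
#'
#' @param counts Numeric matrix with feature rownames and sample colnames.
#' @param path Output TSV path.
#' @param id_col Name for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, id_col = "feature_id") {
  df <- data.frame(counts, check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(counts)), id_col), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample clinical metadata
#'
#' Expected TSV header: `sample_id  subtype  gcnis  stage`.
#'
#' @param path File path.
#' @return A `data.frame` with those columns as character.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "subtype", "gcnis", "stage")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata table ", path, " missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Read a tumour-versus-normal fold-change table
#'
#' Expected TSV header: `mirna_id  fold_change` (linear ratio, tumour over
#' normal).
#'
#' @param path File path.
#' @param cohort_id Cohort label; defaults to the file name without
#'   extension.
#' @return A `data.frame` with `mirna_id`, `fold_change`, `cohort_id`.
#' @export
read_fold_changes <- function(path, cohort_id = NULL) {
  if (is.null(cohort_id))
    cohort_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "fold_change") %in% names(df)))
    stop("fold-change table ", path,
         " must have columns mirna_id, fold_change", call. = FALSE)
  df$cohort_id <- cohort_id
  df[c("mirna_id", "fold_change", "cohort_id")]
}

#' Read a miRNA name alias table
#'
#' Expected TSV header: `raw_name  canonical_id`. Conflicting rows (one raw
#' name mapped to two canonical ids) are rejected at load time.
#'
#' @param path File path.
#' @return A named character vector: `names()` are raw names, values are
#'   canonical ids.
#' @export
read_alias_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("raw_name", "canonical_id") %in% names(df)))
    stop("alias table must have columns raw_name, canonical_id",
         call. = FALSE)
  df <- unique(df[c("raw_name", "canonical_id")])
  if (anyDuplicated(df$raw_name)) {
    dup <- df$raw_name[duplicated(df$raw_name)][1]
    stop("conflicting aliases for '", dup, "' in ", path, call. = FALSE)
  }
  stats::setNames(df$canonical_id, df$raw_name)
}

#' Read per-algorithm target-prediction lists
#'
#' One TSV per algorithm with a `gene_id` column; the algorithm name defaults
#' to the file name without extension.
#'
#' @param paths Character vector of file paths.
#' @param algorithms Optional algorithm names, parallel to `paths`.
#' @return A named list of character gene-id sets.
#' @export
read_target_sets <- function(paths, algorithms = NULL) {
  if (is.null(algorithms))
    algorithms <- sub("\\.[^.]*$", "", basename(paths))
  out <- lapply(paths, function(p) {
    df <- utils::read.delim(p, stringsAsFactors = FALSE, comment.char = "#")
    if (!"gene_id" %in% names(df))
      stop("target list ", p, " must have a gene_id column", call. = FALSE)
    unique(df$gene_id)
  })
  stats::setNames(out, algorithms)
}

#' Read a gene-to-cytoband map
#'
#' Expected TSV header: `gene_id  band` (e.g. `12p13.31`).
#'
#' @param path File path.
#' @return Named character vector: names are gene ids, values band labels.
#' @export
read_cytoband_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "band") %in% names(df)))
    stop("cytoband map must have columns gene_id, band", call. = FALSE)
  stats::setNames(df$band, df$gene_id)
}

#' Read a long-format qPCR Ct table
#'
#' Expected TSV header: `sample  gene  replicate  ct`; Ct values must be
#' finite and positive.
#'
#' @param path File path.
#' @return A `data.frame` with those columns.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("Ct table ", path, " missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$ct) | df$ct <= 0))
    stop("Ct values must be finite and positive", call. = FALSE)
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
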