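#' Library-size normalization to log2 counts-per-million
#'
#' Each sample (column) is scaled to a common library size of one million and
#' shifted through `log2(x + 1)`. Deterministic, and invariant to multiplying
#' all counts of a sample by a constant.
#'
#' @param counts Non-negative numeric matrix, features x samples, with
#'   rownames and colnames.
#' @return Matrix of the same shape on the log2 scale.
#' @export
normalize_log2 <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("all-zero sample: ",
         paste(colnames(counts)[lib == 0], collapse = ", "), call. = FALSE)
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  log2(cpm + 1)
}

new_stratification <- function(strata, driver, cutoffs) {
  structure(list(strata = strata, driver = driver, cutoffs = cutoffs),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat(sprintf("<stratification> driver %s: %s (cutoffs: %s)\n",
              x$driver,
              paste(sprintf("%s=%d", names(table(x$strata)),
                            as.integer(table(x$strata))), collapse = " "),
              paste(signif(x$cutoffs, 6), collapse = ", ")))
  invisible(x)
}

#' Tertile stratification of samples by driver expression
#'
#' Samples are sorted descending by the driver value (ties broken by stable
#' sample-id order) and split at the 1/3 and 2/3 rank boundaries into high
#' (H), medium (M) and low (L) strata; sizes differ by at most one.
#'
#' @param expr Named numeric vector of per-sample driver expression.
#' @param driver Driver feature id recorded on the result.
#' @return A `stratification`: `$strata` is a named factor with levels
#'   `H`, `M`, `L`; `$cutoffs` holds the two boundary values actually used
#'   (the minimum driver value admitted to H and to M).
#' @export
stratify_tertiles <- function(expr, driver = "driver") {
  n <- length(expr)
  if (n < 3L) stop("need at least 3 samples to form tertiles", call. = FALSE)
  if (is.null(names(expr))) names(expr) <- paste0("S", seq_len(n))
  ord <- order(-expr, names(expr))
  b1 <- round(n / 3)
  b2 <- round(2 * n / 3)
  lab <- rep(c("H", "M", "L"), c(b1, b2 - b1, n - b2))
  strata <- factor(stats::setNames(lab[order(ord)], names(expr)),
                   levels = c("H", "M", "L"))
  names(strata) <- names(expr)
  cutoffs <- c(H = unname(expr[ord[b1]]), M = unname(expr[ord[b2]]))
  new_stratification(strata, driver, cutoffs)
}

#' Stratify samples at fixed driver cutoffs
#'
#' One cutoff yields two strata (H/L), two cutoffs yield three (H/M/L).
#' Samples exactly at a boundary are assigned to the upper stratum.
#'
#' @param expr Named numeric vector of per-sample driver expression.
#' @param cutoffs One or two boundary values (sorted ascending internally).
#' @param driver Driver feature id recorded on the result.
#' @return A `stratification` (see [stratify_tertiles()]).
#' @export
stratify_by_cutoff <- function(expr, cutoffs, driver = "driver") {
  stopifnot(length(cutoffs) %in% c(1L, 2L))
  cutoffs <- sort(cutoffs)
  if (is.null(names(expr))) names(expr) <- paste0("S", seq_along(expr))
  if (length(cutoffs) == 1L) {
    lab <- ifelse(expr >= cutoffs, "H", "L")
    lev <- c("H", "L")
  } else {
    lab <- ifelse(expr >= cutoffs[2], "H", ifelse(expr >= cutoffs[1], "M", "L"))
    lev <- c("H", "M", "L")
  }
  strata <- factor(lab, levels = lev)
  names(strata) <- names(expr)
  new_stratification(strata, driver, cutoffs)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated front end to `stats::p.adjust(method = "BH")`; input order
#' is preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

rank_sum_p <- function(a, b) {
  if (stats::var(c(a, b)) == 0) return(1)
  stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
}

#' Differential expression between two sample groups
#'
#' A two-sided Wilcoxon rank-sum test per feature on normalized log2 values,
#' with a log2 fold change computed as `mean(A) - mean(B)` and BH adjustment
#' across all tested features. A feature is called significant only if it
#' also clears the mean-expression floor (`mean_log2 > expression_floor`).
#' This is a deliberately simple, fully specified stand-in for count-model DE
#' fits; it preserves the decision thresholds of the downstream cascade.
#'
#' @param norm Normalized matrix from [normalize_log2()].
#' @param group_a,group_b Disjoint character vectors of sample ids, each of
#'   size >= 2.
#' @param alpha FDR threshold for significance (default 0.05).
#' @param expression_floor Minimum mean log2 expression across both groups
#'   (default 1.0).
#' @return A `data.frame` (class `de_result`) with columns `feature_id`,
#'   `log2fc`, `mean_log2`, `p`, `fdr`, `direction` (`up`/`down`, `NA` at
#'   exactly zero fold change), `significant`.
#' @export
differential_expression <- function(norm, group_a, group_b,
                                    alpha = 0.05, expression_floor = 1.0) {
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint", call. = FALSE)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  miss <- setdiff(c(group_a, group_b), colnames(norm))
  if (length(miss))
    stop("samples not in matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  A <- norm[, group_a, drop = FALSE]
  B <- norm[, group_b, drop = FALSE]
  log2fc <- rowMeans(A) - rowMeans(B)
  mean_log2 <- rowMeans(cbind(A, B))
  p <- vapply(seq_len(nrow(norm)),
              function(i) rank_sum_p(A[i, ], B[i, ]), 0)
  fdr <- bh_adjust(p)
  out <- data.frame(
    feature_id = rownames(norm),
    log2fc = unname(log2fc),
    mean_log2 = unname(mean_log2),
    p = p,
    fdr = fdr,
    direction = ifelse(log2fc > 0, "up",
                       ifelse(log2fc < 0, "down", NA_character_)),
    significant = unname(mean_log2 > expression_floor & fdr < alpha),
    stringsAsFactors = FALSE
  )
  attr(out, "method") <- "wilcoxon-rank-sum on log2-CPM (count-model stand-in)"
  attr(out, "alpha") <- alpha
  attr(out, "expression_floor") <- expression_floor
  class(out) <- c("de_result", "data.frame")
  out
}

#' Spearman correlation between samples
#'
#' @param norm Normalized matrix (features x samples), >= 2 samples and >= 2
#'   features.
#' @return Symmetric sample x sample correlation matrix with unit diagonal.
#'   Constant (zero-variance) samples yield `NA` correlations and are listed
#'   in the `undefined_samples` attribute, with a warning.
#' @export
spearman_matrix <- function(norm) {
  if (ncol(norm) < 2L || nrow(norm) < 2L)
    stop("need at least 2 samples and 2 features", call. = FALSE)
  const <- apply(norm, 2, function(x) stats::var(x) == 0)
  rho <- suppressWarnings(stats::cor(norm, method = "spearman"))
  diag(rho) <- 1
  if (any(const)) {
    warning("constant samples with undefined correlations: ",
            paste(colnames(norm)[const], collapse = ", "), call. = FALSE)
    attr(rho, "undefined_samples") <- colnames(norm)[const]
  }
  rho
}

#' Complete-linkage clustering order from a correlation matrix
#'
#' Agglomerative clustering on the dissimilarity `1 - rho` with complete
#' linkage.
#'
#' @param corr Symmetric correlation matrix.
#' @return A list (class `cluster_order`) with `order` (leaf labels left to
#'   right), `merge`, `height` and the underlying `hclust` object.
#' @export
cluster_order <- function(corr) {
  if (!isSymmetric(unname(corr), tol = 1e-8))
    stop("correlation matrix must be symmetric", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(1 - corr), method = "complete")
  structure(list(order = hc$labels[hc$order], merge = hc$merge,
                 height = hc$height, hclust = hc),
            class = "cluster_order")
}

#' @export
print.cluster_order <- function(x, ...) {
  cat("<cluster_order>", length(x$order), "leaves:",
      paste(utils::head(x$order, 8), collapse = " "),
      if (length(x$order) > 8) "..." else "", "\n")
  invisible(x)
}

#' Principal component scores of samples
#'
#' PCA on centred (not scaled) normalized values, samples as observations.
#' The sign of each component is fixed by making its largest-magnitude
#' loading positive, so scores are deterministic.
#'
#' @param norm Normalized matrix (features x samples).
#' @param n_components Number of components to return (default 2).
#' @return Matrix samples x components of scores, with a `loadings`
#'   attribute.
#' @export
pca_scores <- function(norm, n_components = 2) {
  x <- t(norm)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (n_components > ncol(pc$rotation))
    stop("n_components exceeds the rank of the data (",
         ncol(pc$rotation), ")", call. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  sc <- pc$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sc[, j] <- -sc[, j]
    }
  }
  attr(sc, "loadings") <- rot
  sc
}
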