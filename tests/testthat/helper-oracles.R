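# Independent brute-force oracles and random-instance builders.
# These deliberately avoid the package's interval/statistics code paths:
# intervals are expanded to per-base boolean vectors, BH is computed from
# its definition, Spearman from ranks + Pearson, Venn regions from
# membership bitmasks.

random_intervals <- function(n, max_pos = 1000, chrom = "chr1") {
  s <- sample(0:(max_pos - 2), n, replace = TRUE)
  e <- pmin(s + sample(1:60, n, replace = TRUE), max_pos)
  genomic_intervals(rep(chrom, n), s, e)
}

# logical vector over bases 0..max_pos-1 (single chromosome)
cover_bases <- function(gr, max_pos = 1000) {
  v <- logical(max_pos)
  s <- gi_start0(gr); e <- gi_end0(gr)
  for (i in seq_along(s)) v[(s[i] + 1):e[i]] <- TRUE
  v
}

expect_sorted_merged <- function(gr) {
  if (length(gr) < 2) return(invisible(TRUE))
  s <- gi_start0(gr); e <- gi_end0(gr)
  expect_false(is.unsorted(s, strictly = TRUE))
  expect_true(all(s[-1] > e[-length(e)]))  # maximal: gaps strictly positive
  invisible(TRUE)
}

bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

spearman_oracle <- function(m) {
  r <- apply(m, 2, rank)
  stats::cor(r, method = "pearson")
}

venn_oracle_sizes <- function(sets) {
  universe <- unique(unlist(sets))
  counts <- integer(2^length(sets) - 1)
  keys <- character(2^length(sets) - 1)
  out <- list()
  for (el in universe) {
    mask <- vapply(sets, function(s) el %in% s, TRUE)
    key <- paste(names(sets)[mask], collapse = "+")
    out[[key]] <- c(out[[key]], el)
  }
  vapply(out, length, 0L)
}

vote_oracle <- function(sets, gene) {
  sum(vapply(sets, function(s) gene %in% s, TRUE))
}

# brute-force re-derivation of the cascade stages as plain set filters
cascade_oracle_tiers <- function(binding, de, unified, rule, exclusions) {
  tiers <- setNames(rep(NA_integer_, nrow(binding)), binding$mirna_id)
  for (k in seq_len(nrow(binding))) {
    id <- binding$mirna_id[k]
    if (!binding$bound[k]) next
    i <- match(id, de$feature_id)
    if (is.na(i) || !de$significant[i]) next
    lim <- if (binding$genomic_class[k] == "intergenic")
      rule$max_distance_intergenic else rule$max_distance_intronic
    dist_ok <- binding$distance_bp[k] <= lim
    j <- match(id, unified$mirna_id)
    coh_ok <- !is.na(j) && !unified$discordant[j] &&
      !is.na(unified$direction[j]) &&
      identical(unified$direction[j], de$direction[i])
    tiers[id] <- if (dist_ok && coh_ok) 1L else if (dist_ok) 2L else 3L
  }
  tiers[names(tiers) %in% exclusions & !is.na(tiers)] <- NA_integer_
  tiers
}

# a tiny deterministic study used by several files
tiny_study <- function(seed = 11) simulate_study(sim_config(seed = seed))
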