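make_counts <- function(nf = 20, ns = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(rnbinom(nf * ns, mu = 200, size = 5), nf, ns,
              dimnames = list(sprintf("f%02d", 1:nf), sprintf("s%02d", 1:ns)))
  m
}

test_that("log2-CPM normalization: closed form, scale invariance, loop oracle", {
  m <- matrix(c(1023, 1e6 - 1023), 2, 1,
              dimnames = list(c("a", "b"), "s1"))
  expect_equal(normalize_log2(m)["a", "s1"], 10)

  m2 <- make_counts()
  doubled <- m2
  doubled[, 3] <- doubled[, 3] * 2
  expect_equal(normalize_log2(doubled)[, 3], normalize_log2(m2)[, 3])

  # naive per-sample loop oracle
  want <- m2
  for (j in seq_len(ncol(m2)))
    want[, j] <- log2(m2[, j] / sum(m2[, j]) * 1e6 + 1)
  expect_equal(normalize_log2(m2), want)

  m3 <- m2; m3[, 2] <- 0
  expect_error(normalize_log2(m3), "s02")
})

test_that("tertile stratification partitions samples with balanced sizes", {
  x <- setNames(c(9:1), paste0("s", 1:9))
  st <- stratify_tertiles(x)
  expect_equal(as.integer(table(st$strata)), c(3, 3, 3))
  expect_equal(names(st$strata)[st$strata == "H"], c("s1", "s2", "s3"))

  set.seed(4)
  x156 <- setNames(sample(seq_len(1560), 156), sprintf("t%03d", 1:156))
  st156 <- stratify_tertiles(x156)
  expect_equal(as.integer(table(st156$strata)), c(52, 52, 52))
  # all H values >= all M values >= all L values
  expect_gte(min(x156[st156$strata == "H"]), max(x156[st156$strata == "M"]))
  expect_gte(min(x156[st156$strata == "M"]), max(x156[st156$strata == "L"]))

  expect_error(stratify_tertiles(c(a = 1, b = 2)), "at least 3")

  # boundary ties resolved exactly as a brute-force stable sort
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    v <- setNames(sample(1:5, n, replace = TRUE), sprintf("s%02d", 1:n))
    st <- stratify_tertiles(v)
    ord <- order(-v, names(v))  # stable descending with id tie-break
    b1 <- round(n / 3); b2 <- round(2 * n / 3)
    want <- setNames(rep(NA_character_, n), names(v))
    want[ord] <- rep(c("H", "M", "L"), c(b1, b2 - b1, n - b2))
    expect_equal(as.character(st$strata), unname(want[names(v)]))
    expect_true(abs(diff(range(table(st$strata)))) <= 1)
  }
})

test_that("cutoff stratification sends boundary values to the upper stratum", {
  v <- c(a = 13.0, b = 12.288, c = 11.9)
  st <- stratify_by_cutoff(v, 12.288)
  expect_equal(as.character(st$strata), c("H", "H", "L"))

  expect_equal(as.character(stratify_by_cutoff(c(x = 6), c(4, 8))$strata),
               "M")

  # agreement with tertiles when cutoffs sit at the tertile boundaries
  set.seed(5)
  v2 <- setNames(runif(30), sprintf("s%02d", 1:30))  # distinct values
  tert <- stratify_tertiles(v2)
  cut <- stratify_by_cutoff(v2, sort(unname(tert$cutoffs)))
  expect_equal(as.character(cut$strata), as.character(tert$strata))
})

test_that("BH wrapper equals the from-definition oracle and validates input", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  for (rep in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p & adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("differential expression applies both thresholds and is antisymmetric", {
  norm <- normalize_log2(make_counts(nf = 30, ns = 12, seed = 3))
  A <- colnames(norm)[1:6]; B <- colnames(norm)[7:12]

  expect_error(differential_expression(norm, A, c(B, A[1])), "disjoint")
  expect_error(differential_expression(norm, A[1], B), "at least 2")

  de <- differential_expression(norm, A, B)
  de_rev <- differential_expression(norm, B, A)
  expect_equal(de$log2fc, -de_rev$log2fc)
  expect_equal(de$p, de_rev$p)
  expect_equal(de$fdr, de_rev$fdr)
  up <- !is.na(de$direction) & de$direction == "up"
  expect_equal(de$direction[up],
               rep("up", sum(up)))
  expect_true(all(de_rev$direction[up] == "down"))

  # identical values in both groups: null feature
  m0 <- matrix(100, 4, 8, dimnames = list(paste0("f", 1:4), paste0("s", 1:8)))
  de0 <- differential_expression(normalize_log2(m0), paste0("s", 1:4),
                                 paste0("s", 5:8))
  expect_equal(de0$log2fc, rep(0, 4))
  expect_false(any(de0$significant))

  # a feature below the expression floor is never significant, however small
  # its p-value
  lownorm <- rbind(
    low = c(rep(0.6, 6), rep(0.4, 6)),
    rest = seq(2, 3.1, 0.1)
  )
  colnames(lownorm) <- paste0("s", 1:12)
  del <- differential_expression(lownorm, paste0("s", 1:6), paste0("s", 7:12))
  expect_lt(del$fdr[del$feature_id == "low"], 0.05)
  expect_lt(del$mean_log2[del$feature_id == "low"], 1)
  expect_false(del$significant[del$feature_id == "low"])
})

test_that("a planted two-fold-log2 shift is recovered as significant and up", {
  set.seed(77)
  nf <- 50; n <- 20
  mu <- matrix(2^runif(nf, 5, 8), nf, 2 * n)
  mu[1, 1:n] <- mu[1, 1:n] * 4  # +2 on the log2 scale in group A
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 3), nf, 2 * n,
                   dimnames = list(sprintf("f%02d", 1:nf),
                                   sprintf("s%02d", 1:(2 * n))))
  norm <- normalize_log2(counts)
  de <- differential_expression(norm, colnames(norm)[1:n],
                                colnames(norm)[(n + 1):(2 * n)])
  expect_true(de$significant[1])
  expect_equal(de$direction[1], "up")
})

test_that("Spearman matrix matches the rank-then-Pearson oracle", {
  norm <- normalize_log2(make_counts(nf = 40, ns = 6, seed = 9))
  rho <- spearman_matrix(norm)
  expect_true(isSymmetric(rho))
  expect_equal(unname(diag(rho)), rep(1, ncol(norm)))
  expect_equal(rho, spearman_oracle(norm))

  dup <- cbind(norm, dup = norm[, 1])
  expect_equal(spearman_matrix(dup)["s01", "dup"], 1)

  dec <- cbind(norm[, 1, drop = FALSE], flip = -norm[, 1]^3)
  expect_equal(spearman_matrix(dec)[1, 2], -1)

  const <- cbind(norm, flat = rep(5, nrow(norm)))
  expect_warning(rc <- spearman_matrix(const), "flat")
  expect_equal(attr(rc, "undefined_samples"), "flat")
})

test_that("complete-linkage ordering keeps planted blocks contiguous", {
  set.seed(10)
  base1 <- rnorm(60); base2 <- rnorm(60) + 4
  m <- cbind(sapply(1:4, function(i) base1 + rnorm(60, sd = 0.1)),
             sapply(1:4, function(i) base2 + rnorm(60, sd = 0.1)))
  colnames(m) <- c(paste0("a", 1:4), paste0("b", 1:4))
  rho <- spearman_matrix(m)
  co <- cluster_order(rho)
  grp <- substr(co$order, 1, 1)
  expect_equal(length(rle(grp)$lengths), 2)  # each block contiguous
  expect_true(all(diff(co$height) >= -1e-12))

  # three samples with one clear pair: the pair merges first
  rho3 <- matrix(c(1, .95, .1, .95, 1, .12, .1, .12, 1), 3, 3,
                 dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  co3 <- cluster_order(rho3)
  expect_equal(sort(co3$merge[1, ]), c(-2, -1))

  expect_error(cluster_order(matrix(c(1, .2, .5, 1), 2, 2)), "symmetric")
})

test_that("PCA scores are deterministic, separating, and variance-bounded", {
  set.seed(11)
  m <- cbind(matrix(rnorm(200, 0), 50, 4), matrix(rnorm(200, 3), 50, 4))
  colnames(m) <- c(paste0("a", 1:4), paste0("b", 1:4))
  rownames(m) <- paste0("f", 1:50)
  sc <- pca_scores(m)
  pc1 <- sc[, 1]
  expect_true(max(pc1[1:4]) < min(pc1[5:8]) ||
                min(pc1[1:4]) > max(pc1[5:8]))

  dup <- cbind(m, a1copy = m[, 1])
  scd <- pca_scores(dup)
  expect_equal(unname(scd["a1copy", ]), unname(scd["a1", ]))

  expect_lte(sum(apply(sc, 2, var)), sum(apply(t(m), 2, var)) + 1e-8)
  expect_error(pca_scores(m, n_components = 50), "rank")

  # sign convention: largest-magnitude loading positive
  ld <- attr(sc, "loadings")
  for (j in 1:2) expect_gt(ld[which.max(abs(ld[, j])), j], 0)
})
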