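test_that("intersection matches worked overlaps and rejects bad intervals", {
  a <- genomic_intervals("chr1", 100, 200)
  b <- genomic_intervals("chr1", 150, 250)
  out <- intersect_interval_sets(a, b)
  expect_equal(gi_start0(out), 150)
  expect_equal(gi_end0(out), 200)

  empty <- genomic_intervals(character(), numeric(), numeric())
  expect_length(intersect_interval_sets(a, empty), 0)

  expect_error(genomic_intervals("chr1", 200, 100, name = "badrec"),
               "badrec")
  expect_error(genomic_intervals("chr1", 50, 50), "invalid interval")
})

test_that("intersection equals the per-base oracle on random instances", {
  set.seed(42)
  for (rep in 1:20) {
    a <- random_intervals(50)
    b <- random_intervals(50)
    out <- intersect_interval_sets(a, b)
    expect_sorted_merged(out)
    want <- cover_bases(a) & cover_bases(b)
    got <- if (length(out)) cover_bases(out) else logical(1000)
    expect_identical(got, want)
  }
})

test_that("intersection is commutative and associative (per-base oracle)", {
  set.seed(7)
  for (rep in 1:5) {
    a <- random_intervals(20)
    b <- random_intervals(20)
    c <- random_intervals(20)
    ab <- intersect_interval_sets(a, b)
    ba <- intersect_interval_sets(b, a)
    expect_identical(cover_bases(ab), cover_bases(ba))
    abc1 <- intersect_interval_sets(ab, c)
    abc2 <- intersect_interval_sets(a, intersect_interval_sets(b, c))
    expect_identical(cover_bases(abc1), cover_bases(abc2))
    expect_identical(cover_bases(abc1),
                     cover_bases(a) & cover_bases(b) & cover_bases(c))
  }
})

test_that("replicate consensus is the strict per-base AND", {
  one <- genomic_intervals("chr1", 5, 15)
  expect_equal(gi_start0(consensus_across_replicates(list(one))), 5)
  expect_equal(gi_end0(consensus_across_replicates(list(one))), 15)

  reps <- list(genomic_intervals("chr1", 0, 10),
               genomic_intervals("chr1", 5, 15),
               genomic_intervals("chr1", 8, 20))
  out <- consensus_across_replicates(reps)
  expect_equal(gi_start0(out), 8)
  expect_equal(gi_end0(out), 10)

  expect_error(consensus_across_replicates(list()), "at least one")

  set.seed(9)
  for (rep in 1:10) {
    rs <- replicate(3, random_intervals(30), simplify = FALSE)
    out <- consensus_across_replicates(rs)
    want <- Reduce(`&`, lapply(rs, cover_bases))
    got <- if (length(out)) cover_bases(out) else logical(1000)
    expect_identical(got, want)
  }
})

test_that("upstream windows are strand-aware, abutting, and clipped at 0", {
  # plus-strand locus on the published deletion scale
  loc <- mirna_loci("MIR9-2", "chr5", 88666888, 88667345, "+", "intergenic")
  w <- upstream_window(loc, 2000)
  expect_equal(gi_start0(w), 88664888)
  expect_equal(gi_end0(w), 88666888)

  locm <- mirna_loci("m", "chr1", 100, 200, "-", "intergenic")
  wm <- upstream_window(locm, 50)
  expect_equal(gi_start0(wm), 200)
  expect_equal(gi_end0(wm), 250)

  locc <- mirna_loci("c", "chr1", 10, 50, "+", "intergenic")
  wc <- upstream_window(locc, 100)
  expect_equal(gi_start0(wc), 0)
  expect_equal(gi_end0(wc), 10)

  locu <- mirna_loci("u", "chr1", 10, 50, ".", "intergenic")
  expect_error(upstream_window(locu, 100), "undefined")

  # window length = k unless clipped; window never overlaps its locus
  set.seed(13)
  for (rep in 1:20) {
    s <- sample(0:5000, 1); len <- sample(50:400, 1)
    str <- sample(c("+", "-"), 1)
    l <- mirna_loci("x", "chr1", s, s + len, str, "intergenic")
    k <- sample(c(500, 1000, 2000), 1)
    w <- upstream_window(l, k)
    expect_lte(interval_length(w), k)
    if (str == "-" || s >= k) expect_equal(interval_length(w), k)
    ov <- intersect_interval_sets(w, loci_gr <- genomic_intervals("chr1", s, s + len))
    expect_length(ov, 0)
  }
})

test_that("interval length is end minus start", {
  d <- genomic_intervals("chr5", 88667031, 88667060)
  expect_equal(interval_length(d), 29)
  expect_equal(interval_length(genomic_intervals("chr1", 0, 1)), 1)
  set.seed(3)
  for (rep in 1:10) {
    g <- random_intervals(1)
    expect_equal(interval_length(g), sum(cover_bases(g)))
  }
})

test_that("binding assignment grades windows and measures the 5' gap", {
  loci <- mirna_loci(c("a", "b", "c"), "chr1",
                     c(50000, 50000, 50000), c(50100, 50100, 50100),
                     "+", "intergenic")
  # peak wholly inside the 2 kb window; peak 6 kb upstream; peak 12 kb away
  peaks <- genomic_intervals("chr1",
                             c(50000 - 1500, 50000 - 6400, 50000 - 12400),
                             c(50000 - 1100, 50000 - 6000, 50000 - 12000))
  ba <- assign_binding(loci[1, ], peaks[1], factor = "NANOG")
  expect_true(ba$bound)
  expect_equal(ba$smallest_window_kb, 2)
  expect_equal(ba$distance_bp, 1100)

  ba2 <- assign_binding(loci[2, ], peaks[2])
  expect_equal(ba2$smallest_window_kb, 10)
  expect_equal(ba2$distance_bp, 6000)

  ba3 <- assign_binding(loci[3, ], peaks[3])
  expect_false(ba3$bound)
  expect_true(is.na(ba3$smallest_window_kb))

  # peak covering the 5' end itself: distance 0, smallest window 1 kb
  pk0 <- genomic_intervals("chr1", 49950, 50050)
  ba0 <- assign_binding(loci[1, ], pk0)
  expect_equal(ba0$distance_bp, 0)
  expect_equal(ba0$smallest_window_kb, 1)
})

test_that("window monotonicity: bound within k1 implies bound within k2 > k1", {
  set.seed(21)
  st <- tiny_study()
  cons <- consensus_across_replicates(st$chip)
  prev <- rep(FALSE, nrow(st$annotation))
  for (k in c(1, 2, 5, 10)) {
    b <- assign_binding(st$annotation, cons, windows_kb = k)
    expect_true(all(b$bound[prev]))  # bound at k1 stays bound at k2 > k1
    prev <- b$bound
  }
  # distance never exceeds the smallest window
  ba <- assign_binding(st$annotation, cons)
  bd <- ba[ba$bound, ]
  expect_true(all(bd$distance_bp <= bd$smallest_window_kb * 1000))
})

test_that("binding is invariant under strand reversal with mirrored coordinates", {
  st <- tiny_study(seed = 5)
  cons <- consensus_across_replicates(st$chip)
  ba <- assign_binding(st$annotation, cons)

  C <- 2e7  # reflection point beyond every coordinate
  ann <- st$annotation
  mirrored <- mirna_loci(ann$mirna_id, ann$chrom,
                         C - ann$end, C - ann$start,
                         ifelse(ann$strand == "+", "-", "+"),
                         ann$genomic_class, ann$host_gene)
  mcons <- genomic_intervals(as.character(GenomeInfoDb::seqnames(cons)),
                             C - gi_end0(cons), C - gi_start0(cons))
  mba <- assign_binding(mirrored, mcons)
  expect_equal(mba$bound, ba$bound)
  expect_equal(mba$smallest_window_kb, ba$smallest_window_kb)
  expect_equal(mba$distance_bp, ba$distance_bp)
})
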