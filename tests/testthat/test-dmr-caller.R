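test_that("tiling snaps to the fixed genome grid without clipping", {
  panel <- genomic_intervals("chr1", 250, 450)
  tiles <- make_tiles(panel, 200)
  expect_equal(tiles$start, c(200, 400))
  expect_equal(tiles$end, c(400, 600))

  exact <- make_tiles(genomic_intervals("chr1", 200, 400), 200)
  expect_equal(nrow(exact), 1)
  expect_equal(c(exact$start, exact$end), c(200, 400))

  empty <- make_tiles(genomic_intervals(character(0), numeric(0), numeric(0)))
  expect_equal(nrow(empty), 0)
  expect_error(make_tiles(panel, 0), "tile_size")

  # overlapping panel regions yield unique sorted tiles
  tiles2 <- make_tiles(genomic_intervals("chr1", c(250, 350), c(450, 500)), 200)
  expect_equal(tiles2$start, c(200, 400))
})

test_that("tile aggregation pools counts; pooled level equals weighted mean", {
  tiles <- make_tiles(genomic_intervals("chr1", 0, 400), 200)
  cs <- cpg_calls("chr1", c(50, 150, 250), c(3, 27, 5), c(10, 30, 10),
                  sample_id = "s1")
  tm <- aggregate_tile_counts(tiles, list(s1 = cs))
  expect_equal(tm$meth[, 1], c(30, 5), ignore_attr = TRUE)
  expect_equal(tm$total[, 1], c(40, 10), ignore_attr = TRUE)
  expect_equal(tm$level[1, 1], 0.75)  # = weighted mean of 0.3 and 0.9
  expect_equal(tm$level[1, 1],
               weighted.mean(c(0.3, 0.9), c(10, 30)))

  # tile without CpGs: NA level, zero counts
  tiles3 <- make_tiles(genomic_intervals("chr1", 0, 600), 200)
  tm3 <- aggregate_tile_counts(tiles3, list(s1 = cs))
  expect_true(is.na(tm3$level[3, 1]))
  expect_equal(tm3$total[3, 1], 0, ignore_attr = TRUE)
})

test_that("pooled tile level equals coverage-weighted CpG mean on random data", {
  set.seed(13)
  for (rep in 1:5) {
    pos <- sort(sample(0:1999, 60))
    tot <- rpois(60, 20) + 1
    cs <- cpg_calls("chr1", pos, rbinom(60, tot, runif(1)), tot)
    tiles <- make_tiles(genomic_intervals("chr1", 0, 2000), 200)
    tm <- aggregate_tile_counts(tiles, list(s = cs))
    for (i in seq_len(nrow(tiles))) {
      inside <- pos >= tiles$start[i] & pos < tiles$end[i]
      if (!any(inside)) next
      expect_equal(tm$level[i, 1],
                   weighted.mean(cs$meth_reads[inside] / cs$total_reads[inside],
                                 cs$total_reads[inside]),
                   tolerance = 1e-15)
    }
  }
})

test_that("coverage filter needs >10 reads in >=70% of samples", {
  tot <- matrix(5, nrow = 3, ncol = 10,
                dimnames = list(NULL, paste0("s", 1:10)))
  tot[1, 1:7] <- 11   # 7/10 samples above 10 -> retained
  tot[2, 1:6] <- 11   # 6/10 -> dropped
  tot[3, 1:7] <- 10   # exactly 10 does not count (strict >)
  tm <- make_tile_matrix(meth = tot * 0, total = tot)
  tm <- coverage_filter(tm, min_reads = 10, min_sample_frac = 0.7)
  expect_equal(tm$retained, c(TRUE, FALSE, FALSE))
})

test_that("Fisher two-sided p matches enumerated hypergeometric values", {
  expect_equal(fisher_exact(c(5, 5), c(5, 5)), 1)
  expect_equal(fisher_exact(c(10, 0), c(0, 10)), 2 / 184756, tolerance = 1e-12)
  expect_equal(fisher_exact(c(9, 1), c(1, 9)), 202 / 184756, tolerance = 1e-12)
  expect_error(fisher_exact(c(-1, 5), c(2, 2)), "non-negative")
  expect_error(fisher_exact(c(0, 0), c(2, 2)), ">= 1 read")
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(17)
  for (i in 1:200) {
    m1 <- sample(0:20, 1); u1 <- sample(0:20, 1)
    m2 <- sample(0:20, 1); u2 <- sample(0:20, 1)
    if (m1 + u1 == 0 || m2 + u2 == 0) next
    ours <- fisher_exact(c(m1, u1), c(m2, u2))
    ref <- stats::fisher.test(matrix(c(m1, u1, m2, u2), 2, byrow = TRUE))$p.value
    expect_equal(ours, min(1, ref), tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the step-up formula and its properties", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(19)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))^2
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))  # monotone along sorted p
  }
})

test_that("pairwise DMR calling applies q and delta thresholds", {
  # 6 identical background tiles + one strongly differential + one with a
  # large p but big delta at tiny coverage is excluded by the filter design:
  # here all tiles are retained, thresholds do the work.
  meth <- matrix(c(40, 40), nrow = 8, ncol = 2, byrow = TRUE,
                 dimnames = list(NULL, c("s1", "s2")))
  total <- matrix(80, 8, 2, dimnames = list(NULL, c("s1", "s2")))
  meth[7, ] <- c(10, 70)       # delta -0.75, tiny p  -> called, hypo in s1
  meth[8, ] <- c(30, 46)       # delta -0.2 < 0.3     -> not called
  tm <- make_tile_matrix(meth, total)
  dmrs <- call_pairwise_dmrs(tm, c("s1", "s2"))
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$direction, "hypo")
  expect_equal(c(dmrs$start, dmrs$end), c(1200, 1400))
  tests <- attr(dmrs, "tests")
  expect_true(all(tests$q_value >= tests$p_value - 1e-15))
  expect_error(call_pairwise_dmrs(tm, c("s1", "nope")), "unknown sample")
})

test_that("significant tiles merge below 400 bp gaps and split at 400", {
  mk <- function(starts) {
    n <- length(starts)
    meth <- matrix(c(5, 75), n, 2, byrow = TRUE,
                   dimnames = list(NULL, c("s1", "s2")))
    total <- matrix(80, n, 2, dimnames = list(NULL, c("s1", "s2")))
    make_tile_matrix(meth, total, starts = starts)
  }
  # tiles [0,200) and [400,600): gap 200 < 400 -> one DMR spanning [0,600)
  one <- call_pairwise_dmrs(mk(c(0, 400)), c("s1", "s2"))
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(0, 600))
  expect_equal(one$n_tiles, 2)
  # tiles [0,200) and [600,800): gap 400, not < 400 -> two DMRs
  two <- call_pairwise_dmrs(mk(c(0, 600)), c("s1", "s2"))
  expect_equal(nrow(two), 2)
  # smaller merge distance (200) keeps a 200-bp gap unmerged
  two200 <- call_pairwise_dmrs(mk(c(0, 400)), c("s1", "s2"), merge_dist = 200)
  expect_equal(nrow(two200), 2)
})

test_that("pair order only flips DMR direction", {
  set.seed(23)
  n <- 30
  meth <- cbind(s1 = rbinom(n, 60, 0.2), s2 = rbinom(n, 60, 0.8))
  total <- matrix(60, n, 2, dimnames = list(NULL, c("s1", "s2")))
  tm <- make_tile_matrix(meth, total)
  d12 <- call_pairwise_dmrs(tm, c("s1", "s2"))
  d21 <- call_pairwise_dmrs(tm, c("s2", "s1"))
  expect_equal(d12[, c("chrom", "start", "end", "n_tiles")],
               d21[, c("chrom", "start", "end", "n_tiles")])
  expect_true(all(d12$direction == "hypo"))
  expect_true(all(d21$direction == "hyper"))
})

test_that("tiles uncovered in one sample are skipped, not imputed", {
  meth <- matrix(c(10, 0), 2, 2, byrow = FALSE,
                 dimnames = list(NULL, c("s1", "s2")))
  total <- matrix(c(20, 20, 20, 0), 2, 2, dimnames = list(NULL, c("s1", "s2")))
  tm <- make_tile_matrix(meth, total)
  dmrs <- call_pairwise_dmrs(tm, c("s1", "s2"))
  expect_equal(nrow(attr(dmrs, "tests")), 1)  # only the doubly-covered tile
})

test_that("dynamic fraction counts tiles significant in any pair", {
  # identical samples: nothing dynamic
  total <- matrix(80, 10, 3, dimnames = list(NULL, c("s1", "s2", "s3")))
  tm0 <- make_tile_matrix(total * 0.5, total)
  expect_equal(dynamic_fraction(tm0)$fraction, 0)

  # every tile extreme between s1 and s3 -> fraction 1
  meth <- cbind(s1 = rep(4, 10), s2 = rep(4, 10), s3 = rep(76, 10))
  tm1 <- make_tile_matrix(meth, total)
  expect_equal(dynamic_fraction(tm1)$fraction, 1)
  expect_error(dynamic_fraction(make_tile_matrix(
    cbind(s1 = rep(1, 3)), cbind(s1 = rep(10, 3)))), ">= 2 samples")
})

test_that("DMR matching splits shared vs query-only at the 300-bp rule", {
  ref <- genomic_intervals("chr1", 10000, 11000)
  q <- genomic_intervals("chr1", c(10500, 11250, 11301, 50000),
                         c(10600, 11350, 11400, 50100),
                         name = c("overlap", "near", "at301", "far"))
  m <- match_dmr_sets(q, ref, within_bp = 300)
  expect_equal(sort(m$shared$name), c("near", "overlap"))
  expect_equal(sort(m$query_only$name), c("at301", "far"))
  # gap of exactly 300 bp is still shared (inclusive)
  at300 <- genomic_intervals("chr1", 11300, 11400)
  expect_equal(nrow(match_dmr_sets(at300, ref, 300)$shared), 1)
  # empty reference: everything query-only
  empty <- genomic_intervals(character(0), numeric(0), numeric(0))
  expect_equal(nrow(match_dmr_sets(q, empty)$query_only), 4)
})
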