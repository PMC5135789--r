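test_that("dynamic CpG counting uses the max-min pairwise difference", {
  m <- matrix(c(0.2, 0.6), ncol = 2)  # diff 0.4
  expect_equal(dynamic_cpg_count(m, 0.3), 1)
  const <- matrix(0.5, nrow = 4, ncol = 3)
  expect_equal(dynamic_cpg_count(const, 0.3), 0)
  m3 <- matrix(c(0.10, 0.45,   # 0.35
                 0.10, 0.30,   # 0.20
                 0.10, 0.41),  # 0.31
               ncol = 2, byrow = TRUE)
  expect_equal(dynamic_cpg_count(m3, 0.3), 2)
  expect_error(dynamic_cpg_count(matrix(0.5, 2, 1)), ">= 2 samples")
})

test_that("candidate filter applies repeat, dynamic-CpG, length and chromosome rules", {
  cands <- five_region_fixture()
  filt <- filter_candidates(cands, design_config())
  expect_equal(filt$intervals$name, c("r1", "r5"))
  # inclusive repeat boundary: 0.6 kept, 0.7 dropped (r5 vs r3 above);
  # exclusive comparator drops the boundary region too
  strict <- filter_candidates(cands, design_config(repeat_inclusive = FALSE))
  expect_equal(strict$intervals$name, "r1")
  # idempotent, output subset of input
  again <- filter_candidates(filt, design_config())
  expect_equal(again$intervals, filt$intervals)
  expect_true(all(filt$intervals$name %in% cands$intervals$name))
})

test_that("region scores are min-max rescaled and summed as hand-computed", {
  iv <- genomic_intervals("chr1", c(1000, 3000, 5000), c(1200, 3400, 5400),
                          name = c("A", "B", "C"))
  sl <- matrix(c(0.1, 0.9, 0.3, 0.7, 0.45, 0.55), ncol = 2, byrow = TRUE,
               dimnames = list(iv$name, c("s1", "s2")))
  cl <- list(
    A = matrix(c(0.1, 0.9), 4, 2, byrow = TRUE),   # 4 dynamic CpGs / 200 bp
    B = matrix(c(0.3, 0.7), 4, 2, byrow = TRUE),   # 4 / 400 bp
    C = matrix(c(0.2, 0.6), 2, 2, byrow = TRUE))   # 2 / 400 bp
  for (i in seq_along(cl)) colnames(cl[[i]]) <- c("s1", "s2")
  cands <- make_candidates(iv, sl, cl, repeat_frac = rep(0, 3))
  enh <- genomic_intervals("chr1", 1100, 1300)     # overlaps A only
  sc <- score_regions(cands, enh, NULL, diff_threshold = 0.3)
  sc <- sc[match(c("A", "B", "C"), sc$region_id), ]
  expect_equal(sc$density, c(4 / 200, 4 / 400, 2 / 400))
  expect_equal(sc$max_diff, c(0.8, 0.4, 0.1))
  expect_equal(sc$overlap_flag, c(1, 0, 0))
  # hand-applied min-max arithmetic: A attains every maximum, C every minimum
  expect_equal(sc$score[sc$region_id == "A"], 3)
  expect_equal(sc$score[sc$region_id == "C"], 0)
  expect_equal(sc$score[sc$region_id == "B"],
               (0.01 - 0.005) / (0.02 - 0.005) + (0.4 - 0.1) / (0.8 - 0.1) + 0)
  # rescaled components live in [0,1] and hit both ends
  for (comp in c("density_scaled", "max_diff_scaled", "overlap_scaled")) {
    expect_true(all(sc[[comp]] >= 0 & sc[[comp]] <= 1))
    expect_equal(range(sc[[comp]]), c(0, 1))
  }
})

test_that("a component constant across the set rescales to zero everywhere", {
  iv <- genomic_intervals("chr1", c(0, 1000), c(200, 1200), name = c("A", "B"))
  sl <- matrix(c(0.1, 0.9, 0.3, 0.7), ncol = 2, byrow = TRUE,
               dimnames = list(iv$name, c("s1", "s2")))
  cl <- list(A = matrix(c(0.1, 0.9), 2, 2, byrow = TRUE,
                        dimnames = list(NULL, c("s1", "s2"))),
             B = matrix(c(0.1, 0.9), 2, 2, byrow = TRUE,
                        dimnames = list(NULL, c("s1", "s2"))))
  cands <- make_candidates(iv, sl, cl, repeat_frac = c(0, 0))
  sc <- score_regions(cands, NULL, NULL)  # overlap flag constant 0
  expect_equal(sc$overlap_scaled, c(0, 0))
  expect_equal(sc$density_scaled, c(0, 0))  # same density both regions
})

test_that("origin assignment picks the most hypomethylated sample, ties lexicographic", {
  expect_equal(assign_origin(c(A = 0.1, B = 0.8)), "A")
  expect_equal(assign_origin(c(B = 0.5, A = 0.5)), "A")
  expect_equal(assign_origin(c(Z = 0.2)), "Z")
})

test_that("balanced selection follows the balanced-greedy rule and budget crossing", {
  sc <- make_scored(c("a1", "a2", "b1"), scores = c(3, 2.5, 1),
                    lengths = c(1000, 1000, 1000),
                    origins = c("A", "A", "B"))
  sel <- balanced_select(sc, budget_bp = 3000)
  expect_equal(sel$selected$region_id, c("a1", "b1", "a2"))
  expect_equal(sel$total_bp, 3000)

  sel2 <- balanced_select(sc, budget_bp = 1500)
  expect_equal(sel2$selected$region_id, c("a1", "b1"))
  expect_equal(sel2$total_bp, 2000)  # crossing region kept

  # budget beyond all candidates selects everything
  sel3 <- balanced_select(sc, budget_bp = 1e9)
  expect_equal(sort(sel3$selected$region_id), c("a1", "a2", "b1"))
  expect_error(balanced_select(sc, 0), "budget")
})

test_that("single-origin balanced selection degenerates to greedy by score", {
  set.seed(21)
  n <- 40
  sc <- make_scored(sprintf("r%02d", 1:n), scores = runif(n),
                    lengths = sample(100:900, n), origins = rep("A", n))
  sel <- balanced_select(sc, budget_bp = 5000)
  # oracle: sort by score desc, take until cumulative length >= budget
  o <- order(-sc$score)
  k <- which(cumsum(sc$length[o]) >= 5000)[1]
  expect_equal(sel$selected$region_id, sc$region_id[o][seq_len(k)])
})

test_that("balanced selection keeps origins within one region length of each other", {
  set.seed(22)
  n <- 120
  sc <- make_scored(sprintf("r%03d", 1:n), scores = runif(n),
                    lengths = sample(100:1000, n),
                    origins = sample(LETTERS[1:4], n, replace = TRUE))
  sel <- balanced_select(sc, budget_bp = 20000)
  expect_true(sel$total_bp <= 20000 + max(sc$length))
  # origins with candidates left at termination differ by <= max length
  open <- intersect(unique(sel$remaining$origin), names(sel$origin_bp))
  if (length(open) >= 2)
    expect_true(diff(range(sel$origin_bp[open])) <= max(sc$length))
})

test_that("eQTL augmentation keeps only >=1-bp overlappers in rank order", {
  sc <- make_scored(c("r1", "r2", "r3"), scores = c(3, 2, 1),
                    lengths = c(100, 100, 100), origins = c("A", "B", "C"))
  # r1 spans [10000,10100), r2 [20000,20100), r3 [30000,30100)
  eqtl <- genomic_intervals("chr1", c(10099, 25000), c(10200, 25100))
  aug <- eqtl_augment(sc, eqtl)  # r1 overlaps by exactly 1 bp
  expect_equal(aug$region_id, "r1")
  empty <- genomic_intervals(character(0), numeric(0), numeric(0))
  expect_equal(nrow(eqtl_augment(sc, empty)), 0)
})

test_that("panel assembly merges >=1-base overlaps, keeps bookends, dedupes", {
  a <- genomic_intervals("chr1", 0, 200)
  b <- genomic_intervals("chr1", 100, 300)
  p <- assemble_panel(list(x = a, y = b))
  expect_equal(nrow(p), 1)
  expect_equal(c(p$start, p$end), c(0, 300))
  expect_equal(p$name, "x,y")
  expect_equal(attr(p, "total_bp"), 300)

  # bookended regions are not merged
  p2 <- assemble_panel(list(x = genomic_intervals("chr1", c(0, 200), c(200, 400))))
  expect_equal(nrow(p2), 2)

  # duplicated region across lists appears once
  p3 <- assemble_panel(list(x = a, y = a))
  expect_equal(nrow(p3), 1)

  # disjoint input: sorted concatenation, total is the sum
  d1 <- genomic_intervals(c("chr2", "chr1"), c(500, 0), c(600, 100))
  p4 <- assemble_panel(list(d = d1))
  expect_equal(p4$chrom, c("chr1", "chr2"))
  expect_equal(attr(p4, "total_bp"), 200)

  # assembled panels are pairwise non-overlapping and sorted
  set.seed(31)
  s <- sample.int(1e5, 300)
  rnd <- genomic_intervals("chr1", s, s + sample.int(800, 300))
  p5 <- assemble_panel(list(r = rnd))
  expect_true(all(diff(p5$start) > 0))
  expect_true(all(p5$start[-1] >= p5$end[-nrow(p5)]))
})

test_that("panel summary reports hand-counted overlap percentages", {
  panel <- assemble_panel(list(p = genomic_intervals(
    "chr1", c(0, 1000, 2000, 3000), c(200, 1200, 2200, 3200))))
  track <- genomic_intervals("chr1", c(100, 1100, 9000), c(150, 1150, 9100))
  s <- panel_summary(panel, list(tk = track),
                     cpg_positions = data.frame(chrom = "chr1",
                                                pos = c(50, 1050, 5000)))
  expect_equal(s$n_regions, 4)
  expect_equal(s$total_bp, 800)
  expect_equal(s$n_cpgs, 2)
  expect_equal(s$tracks$n_features_covered, 2)
  expect_equal(s$tracks$pct_features_covered, 2 / 3)
  expect_equal(s$tracks$pct_panel_overlapping, 2 / 4)

  # panel identical to the track: 100% both directions
  s2 <- panel_summary(assemble_panel(list(t = track)), list(tk = track))
  expect_equal(s2$tracks$pct_features_covered, 1)
  expect_equal(s2$tracks$pct_panel_overlapping, 1)

  # empty track: 0%
  empty <- genomic_intervals(character(0), numeric(0), numeric(0))
  s3 <- panel_summary(panel, list(none = empty))
  expect_equal(s3$tracks$pct_features_covered, 0)
})

test_that("candidate sets round-trip through the directory format", {
  cands <- five_region_fixture()
  dir <- tempfile()
  write_candidates(cands, dir)
  back <- read_candidates(dir)
  expect_equal(sort(back$intervals$name), sort(cands$intervals$name))
  expect_equal(back$source, cands$source)
  for (id in cands$intervals$name) {
    expect_equal(unname(back$sample_levels[id, ]),
                 unname(cands$sample_levels[id, ]))
    expect_equal(unname(back$cpg_levels[[id]]), unname(cands$cpg_levels[[id]]))
  }
  expect_equal(back$repeat_frac[match(cands$intervals$name, back$intervals$name)],
               cands$repeat_frac)
})
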