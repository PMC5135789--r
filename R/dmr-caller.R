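#' Tile a target panel on a fixed genomic grid
#'
#' Produces the fixed-width windows `[k*s, (k+1)*s)` of a genome-wide grid
#' (multiples of the tile size) that share at least one base with any panel
#' region. Tiles are full grid windows, never clipped to region edges, so
#' tiles are comparable across panels and runs.
#'
#' @param panel Interval data.frame (e.g. a [meth_panel()]).
#' @param tile_size Tile width in bp (default 200).
#' @return Sorted, unique interval data.frame of tiles.
#' @export
make_tiles <- function(panel, tile_size = 200) {
  if (tile_size <= 0) stop("tile_size must be > 0")
  validate_intervals(panel, "panel")
  if (nrow(panel) == 0)
    return(genomic_intervals(character(0), numeric(0), numeric(0)))
  pieces <- lapply(seq_len(nrow(panel)), function(i) {
    ks <- seq(floor(panel$start[i] / tile_size),
              floor((panel$end[i] - 1) / tile_size))
    data.frame(chrom = panel$chrom[i], start = ks * tile_size,
               end = (ks + 1) * tile_size, stringsAsFactors = FALSE)
  })
  x <- unique(do.call(rbind, pieces))
  x <- sort_intervals(x)
  x$name <- sprintf("%s:%d-%d", x$chrom, as.integer(x$start), as.integer(x$end))
  rownames(x) <- NULL
  x
}

#' Aggregate CpG calls into per-tile methylation counts
#'
#' For each tile and sample, sums methylated and total read counts over the
#' CpGs whose position falls inside the tile. The resulting pooled level
#' `sum(meth) / sum(total)` equals the coverage-weighted mean of the
#' per-CpG levels — the weighted tile methylation used throughout the
#' analysis. Tiles with no covered CpG in a sample carry `NA` level and
#' zero counts.
#'
#' @param tiles Interval data.frame from [make_tiles()].
#' @param callsets List of `cpg_calls` objects (one per sample); names (or
#'   `sample_id` attributes) become sample identifiers.
#' @return A `tile_matrix`: list with `tiles` (interval data.frame),
#'   `samples`, count matrices `meth` and `total` (tiles x samples), level
#'   matrix `level`, and logical `retained` (all `TRUE` until
#'   [coverage_filter()] is applied).
#' @export
aggregate_tile_counts <- function(tiles, callsets) {
  validate_intervals(tiles, "tiles")
  stopifnot(is.list(callsets), length(callsets) >= 1)
  samples <- names(callsets)
  if (is.null(samples))
    samples <- vapply(callsets, function(x) attr(x, "sample_id"), "")
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  nt <- nrow(tiles)
  meth <- total <- matrix(0, nt, length(callsets),
                          dimnames = list(tiles$name, samples))
  for (j in seq_along(callsets)) {
    cs <- as.data.frame(callsets[[j]])
    if (!nrow(cs)) next
    pts <- data.frame(chrom = cs$chrom, start = cs$pos, end = cs$pos + 1)
    h <- interval_hits(pts, tiles)
    if (nrow(h)) {
      meth[, j] <- meth[, j] +
        as.vector(tapply(cs$meth_reads[h$query], factor(h$subject, levels = seq_len(nt)),
                         sum, default = 0))
      total[, j] <- total[, j] +
        as.vector(tapply(cs$total_reads[h$query], factor(h$subject, levels = seq_len(nt)),
                         sum, default = 0))
    }
  }
  level <- meth / total
  level[total == 0] <- NA_real_
  structure(list(tiles = tiles, samples = samples, meth = meth,
                 total = total, level = level, retained = rep(TRUE, nt)),
            class = "tile_matrix")
}

#' Retain tiles with sufficient coverage across the cohort
#'
#' A tile is retained if strictly more than `min_reads` summed CpG reads
#' are present in at least `min_sample_frac` of all samples (inclusive
#' fraction bound, strict read bound).
#'
#' @param tm A `tile_matrix`.
#' @param min_reads Per-sample read-count bound; a sample counts only if its
#'   tile total exceeds this (strict `>`, default 10).
#' @param min_sample_frac Required fraction of samples (default 0.7,
#'   inclusive).
#' @return The `tile_matrix` with its `retained` mask updated.
#' @export
coverage_filter <- function(tm, min_reads = 10, min_sample_frac = 0.7) {
  stopifnot(inherits(tm, "tile_matrix"))
  ok <- rowSums(tm$total > min_reads)
  tm$retained <- ok >= min_sample_frac * length(tm$samples) - 1e-9
  tm
}

#' Two-sided Fisher's exact test on methylated/unmethylated counts
#'
#' Exact two-sided p-value for a 2x2 table of (methylated, unmethylated)
#' calls in two samples, by the probability-mass rule: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' whose probability does not exceed the observed table's. Two-sided
#' conventions differ between implementations; this is the classical rule
#' used by `stats::fisher.test`.
#'
#' @param a,b Length-2 numeric vectors `c(meth, unmeth)` for the two
#'   samples.
#' @return p-value in (0, 1\].
#' @export
fisher_exact <- function(a, b) {
  if (any(c(a, b) < 0)) stop("fisher_exact: counts must be non-negative")
  if (sum(a) < 1 || sum(b) < 1) stop("fisher_exact: each sample needs >= 1 read")
  fisher_exact_counts(a[1], a[2], b[1], b[2])
}

## Vectorised core: two-sided p for tables (m1, u1; m2, u2).
## Hypergeometric: x = m1 with margins (meth total, unmeth total, row1 total).
fisher_exact_counts <- function(m1, u1, m2, u2) {
  n <- max(length(m1), length(u1), length(m2), length(u2))
  m1 <- rep_len(m1, n); u1 <- rep_len(u1, n)
  m2 <- rep_len(m2, n); u2 <- rep_len(u2, n)
  vapply(seq_len(n), function(i) {
    K <- m1[i] + m2[i]          # methylated margin
    Q <- u1[i] + u2[i]          # unmethylated margin
    r <- m1[i] + u1[i]          # sample-1 margin
    xs <- max(0, r - Q):min(r, K)
    d <- stats::dhyper(xs, K, Q, r)
    dobs <- stats::dhyper(m1[i], K, Q, r)
    min(1, sum(d[d <= dobs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: `q_(i) = min_{j >= i}
#' (p_(j) * m / j)`, capped at 1, mapped back to the input order.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

## Per-pair tile tests: Fisher p on pooled counts, BH across tested tiles.
## Returns a data.frame aligned with tested tile indices.
pairwise_tile_tests <- function(tm, pair) {
  stopifnot(inherits(tm, "tile_matrix"), length(pair) == 2)
  miss <- setdiff(pair, tm$samples)
  if (length(miss)) stop("unknown sample id: ", paste(miss, collapse = ", "))
  i1 <- match(pair[1], tm$samples)
  i2 <- match(pair[2], tm$samples)
  testable <- tm$retained & tm$total[, i1] > 0 & tm$total[, i2] > 0
  idx <- which(testable)
  if (!length(idx))
    return(data.frame(tile = integer(0), delta = numeric(0),
                      p_value = numeric(0), q_value = numeric(0)))
  m1 <- tm$meth[idx, i1]; t1 <- tm$total[idx, i1]
  m2 <- tm$meth[idx, i2]; t2 <- tm$total[idx, i2]
  p <- fisher_exact_counts(m1, t1 - m1, m2, t2 - m2)
  data.frame(tile = idx, delta = m1 / t1 - m2 / t2,
             p_value = p, q_value = bh_adjust(p))
}

#' Call differentially methylated regions between two samples
#'
#' For every retained tile covered in both samples, tests the pooled
#' methylated/unmethylated counts with Fisher's exact test, adjusts
#' p-values by Benjamini-Hochberg across the pair's tested tiles, and marks
#' tiles significant when `q <= q_max` and the absolute tile-level
#' methylation difference meets `delta_min`. Significant tiles of the same
#' direction less than `merge_dist` bp apart are merged into DMRs.
#'
#' @param tm A coverage-filtered `tile_matrix`.
#' @param pair Character vector of two sample ids; the reported direction
#'   (`hypo`/`hyper`) refers to the first sample.
#' @param q_max q-value cutoff (default 0.05, inclusive).
#' @param delta_min Minimum absolute methylation difference (default 0.3).
#' @param merge_dist Merge significant tiles with inter-tile gap strictly
#'   below this many bp (default 400).
#' @param delta_strict If `TRUE`, require `|delta| > delta_min` instead of
#'   `>=`.
#' @return A `dmr_set` data.frame with columns `chrom`, `start`, `end`,
#'   `direction`, `n_tiles`, `mean_delta`, `min_q`; attributes `pair` and
#'   `tests` (the per-tile test table).
#' @export
call_pairwise_dmrs <- function(tm, pair, q_max = 0.05, delta_min = 0.3,
                               merge_dist = 400, delta_strict = FALSE) {
  tests <- pairwise_tile_tests(tm, pair)
  dmeets <- if (delta_strict) abs(tests$delta) > delta_min
            else abs(tests$delta) >= delta_min
  tests$significant <- tests$q_value <= q_max & dmeets
  sig <- tests[tests$significant, , drop = FALSE]
  out <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                    direction = character(0), n_tiles = integer(0),
                    mean_delta = numeric(0), min_q = numeric(0),
                    stringsAsFactors = FALSE)
  if (nrow(sig)) {
    tl <- tm$tiles[sig$tile, , drop = FALSE]
    # hypo: first sample lower (delta < 0); merge within direction only
    dir <- ifelse(sig$delta < 0, "hypo", "hyper")
    for (d in unique(dir)) {
      sel <- dir == d
      merged <- merge_with_gap(tl[sel, , drop = FALSE], merge_dist)
      merged$direction <- d
      merged$n_tiles <- vapply(merged$revmap, length, 1L)
      merged$mean_delta <- vapply(merged$revmap, function(i)
        mean(sig$delta[sel][i]), numeric(1))
      merged$min_q <- vapply(merged$revmap, function(i)
        min(sig$q_value[sel][i]), numeric(1))
      merged$revmap <- NULL
      out <- rbind(out, merged)
    }
    out <- out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "pair") <- pair
  attr(out, "tests") <- tests
  class(out) <- c("dmr_set", "data.frame")
  out
}

## Merge intervals whose gap (next start - previous end) is < gap_bp.
merge_with_gap <- function(x, gap_bp) {
  if (nrow(x) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), revmap = I(list())))
  pieces <- list()
  for (ch in unique(x$chrom)) {
    idx <- which(x$chrom == ch)
    red <- IRanges::reduce(.ir(x[idx, , drop = FALSE]),
                           min.gapwidth = gap_bp, with.revmap = TRUE)
    pieces[[ch]] <- data.frame(
      chrom = ch, start = IRanges::start(red) - 1L, end = IRanges::end(red),
      revmap = I(lapply(S4Vectors::mcols(red)$revmap, function(i) idx[i])),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Fraction of tiles dynamically methylated across a cohort
#'
#' Runs every pairwise comparison (Fisher + BH within each pair) and
#' reports the fraction of retained tiles that are significant — q at most
#' `q_max` and absolute difference at least `delta_min` — in at least one
#' pair. The remainder are static.
#'
#' @inheritParams call_pairwise_dmrs
#' @return A list with `fraction`, `n_dynamic`, `n_retained`, and the
#'   logical per-tile `dynamic` vector (indexed over all tiles; `FALSE` for
#'   non-retained tiles).
#' @export
dynamic_fraction <- function(tm, q_max = 0.05, delta_min = 0.3,
                             delta_strict = FALSE) {
  stopifnot(inherits(tm, "tile_matrix"))
  if (length(tm$samples) < 2) stop("dynamic_fraction needs >= 2 samples")
  dyn <- rep(FALSE, nrow(tm$tiles))
  pairs <- utils::combn(tm$samples, 2, simplify = FALSE)
  for (pr in pairs) {
    tests <- pairwise_tile_tests(tm, pr)
    if (!nrow(tests)) next
    dmeets <- if (delta_strict) abs(tests$delta) > delta_min
              else abs(tests$delta) >= delta_min
    sig <- tests$tile[tests$q_value <= q_max & dmeets]
    dyn[sig] <- TRUE
  }
  n_ret <- sum(tm$retained)
  list(fraction = if (n_ret) sum(dyn) / n_ret else NA_real_,
       n_dynamic = sum(dyn), n_retained = n_ret, dynamic = dyn)
}

#' Match a DMR set against a reference interval set
#'
#' Splits query DMRs into those within `within_bp` of (or overlapping) a
#' reference interval ("shared") and the rest ("query_only"). Used to ask
#' which DMRs found in one assay are recoverable by a targeted design.
#'
#' @param query Interval data.frame of DMRs.
#' @param reference Interval data.frame of reference regions.
#' @param within_bp Maximum distance in bp (inclusive; default 300).
#' @return List with data.frames `shared` and `query_only`.
#' @export
match_dmr_sets <- function(query, reference, within_bp = 300) {
  validate_intervals(query, "query")
  validate_intervals(reference, "reference")
  d <- nearest_distance(query, reference)
  shared <- d <= within_bp
  list(shared = query[shared, , drop = FALSE],
       query_only = query[!shared, , drop = FALSE])
}

#' @export
print.tile_matrix <- function(x, ...) {
  cat("Tile matrix: ", nrow(x$tiles), " tiles x ", length(x$samples),
      " samples (", sum(x$retained), " retained)\n", sep = "")
  invisible(x)
}

#' @export
print.dmr_set <- function(x, ...) {
  pr <- attr(x, "pair")
  cat("DMR set: ", nrow(x), " regions",
      if (!is.null(pr)) paste0(" (", pr[1], " vs ", pr[2], ")"), "\n", sep = "")
  if (nrow(x)) print(as.data.frame(x), ...)
  invisible(x)
}

#' Write a pairwise DMR set as BED6
#'
#' Name encodes the sample pair, score is `-log10(q)` capped at 1000 and
#' scaled by 10, strand `+`/`-` encodes hyper/hypomethylation in the first
#' sample.
#'
#' @param dmrs A `dmr_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dmr_bed <- function(dmrs, path) {
  stopifnot(inherits(dmrs, "dmr_set"))
  pr <- attr(dmrs, "pair")
  lines <- if (nrow(dmrs)) {
    score <- pmin(1000, round(-10 * log10(pmax(dmrs$min_q, 1e-100))))
    sprintf("%s\t%d\t%d\t%s\t%d\t%s", dmrs$chrom, as.integer(dmrs$start),
            as.integer(dmrs$end), paste0(pr[1], "_vs_", pr[2]),
            as.integer(score), ifelse(dmrs$direction == "hyper", "+", "-"))
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Write a tile matrix as TSV
#'
#' One row per tile: coordinates, retention flag, then per-sample
#' `meth`/`total`/`level` columns.
#'
#' @param tm A `tile_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tile_matrix <- function(tm, path) {
  stopifnot(inherits(tm, "tile_matrix"))
  df <- data.frame(chrom = tm$tiles$chrom, start = as.integer(tm$tiles$start),
                   end = as.integer(tm$tiles$end), retained = tm$retained)
  for (j in seq_along(tm$samples)) {
    s <- tm$samples[j]
    df[[paste0(s, ".meth")]] <- tm$meth[, j]
    df[[paste0(s, ".total")]] <- tm$total[, j]
    df[[paste0(s, ".level")]] <- round(tm$level[, j], 6)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
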