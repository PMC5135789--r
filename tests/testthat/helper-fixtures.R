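# Small in-code fixtures shared across test files.

# Write lines to a temp file and return its path
tmp_lines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal candidate set: intervals + explicit level matrices
make_candidates <- function(intervals, sample_levels, cpg_levels, repeat_frac,
                            source = "test") {
  candidate_set(intervals, sample_levels, cpg_levels, repeat_frac, source)
}

# The five-region design fixture: exactly two regions survive the filters
# (r2 on chrX, r3 repeat 0.7, r4 length 80 violate one rule each; r5 sits
# on the inclusive repeat boundary 0.6).
five_region_fixture <- function() {
  iv <- genomic_intervals(
    chrom = c("chr1", "chrX", "chr2", "chr2", "chr2"),
    start = c(1000, 1000, 5000, 8000, 2000),
    end   = c(1200, 1200, 5400, 8080, 2400),
    name  = c("r1", "r2", "r3", "r4", "r5"))
  sl <- matrix(c(0.1, 0.9,
                 0.1, 0.9,
                 0.2, 0.8,
                 0.2, 0.8,
                 0.3, 0.7), ncol = 2, byrow = TRUE,
               dimnames = list(iv$name, c("s1", "s2")))
  dyn_cpg <- matrix(c(0.1, 0.9, 0.2, 0.8), ncol = 2, byrow = TRUE,
                    dimnames = list(NULL, c("s1", "s2")))
  cl <- list(r1 = dyn_cpg, r2 = dyn_cpg, r3 = dyn_cpg, r4 = dyn_cpg,
             r5 = dyn_cpg)
  make_candidates(iv, sl, cl, repeat_frac = c(0.2, 0.2, 0.7, 0.2, 0.6))
}

# Scored-region frame for balanced-selection tests (already ranked)
make_scored <- function(ids, scores, lengths, origins) {
  x <- data.frame(region_id = ids, chrom = "chr1",
                  start = seq_along(ids) * 10000,
                  end = seq_along(ids) * 10000 + lengths,
                  length = lengths, source = "test",
                  score = scores, origin = origins,
                  stringsAsFactors = FALSE)
  x <- x[order(-x$score), , drop = FALSE]
  class(x) <- c("scored_regions", "data.frame")
  x
}

# Independent Fisher oracle: explicit enumeration of all tables with the
# observed margins, probabilities from log binomial coefficients.
fisher_oracle <- function(m1, u1, m2, u2) {
  K <- m1 + m2; Q <- u1 + u2; r <- m1 + u1
  xs <- max(0, r - Q):min(r, K)
  logp <- lchoose(K, xs) + lchoose(Q, r - xs) - lchoose(K + Q, r)
  d <- exp(logp)
  dobs <- exp(lchoose(K, m1) + lchoose(Q, u1) - lchoose(K + Q, r))
  min(1, sum(d[d <= dobs * (1 + 1e-7)]))
}

# Hand-applied BH step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Tile matrix built directly from count matrices (tiles on chr1 grid)
make_tile_matrix <- function(meth, total, tile_size = 200, starts = NULL) {
  nt <- nrow(total)
  if (is.null(starts)) starts <- (seq_len(nt) - 1) * tile_size
  tiles <- genomic_intervals("chr1", starts, starts + tile_size,
                             name = paste0("t", seq_len(nt)))
  level <- meth / total
  level[total == 0] <- NA_real_
  structure(list(tiles = tiles, samples = colnames(total), meth = meth,
                 total = total, level = level, retained = rep(TRUE, nt)),
            class = "tile_matrix")
}
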