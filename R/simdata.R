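#' Configuration of the synthetic methylome generator
#'
#' Defines the simulated study: a small multi-chromosome genome with
#' geometrically spaced CpGs, a shared mostly-methylated baseline
#' methylome, planted hypomethylated DMRs affecting random subsets of cell
#' types, Poisson read coverage and binomial methylation counts with a
#' small bisulfite conversion-failure rate.
#'
#' Defaults emulate a targeted bisulfite experiment at desk scale: CpG-dense
#' target territory (mean spacing 50 bp, so a 200-bp tile holds ~4 CpGs),
#' a Beta(8, 2) baseline (mean 0.8, matching a predominantly methylated
#' somatic genome), a planted methylation drop of 0.5, 30x mean coverage,
#' and a 0.4% conversion-failure rate (a 99.6% conversion rate).
#'
#' @param n_chroms Number of chromosomes (default 2).
#' @param chrom_len_bp Length of each chromosome (default 1e6).
#' @param cpg_spacing Mean inter-CpG spacing in bp (default 50).
#' @param n_celltypes Number of cell types (default 2).
#' @param n_dmrs Number of planted DMRs (default 100).
#' @param dmr_len_range Min/max planted DMR length in bp (default 400-1000).
#' @param delta Planted methylation drop in (0, 1\] (default 0.5).
#' @param beta_a,beta_b Baseline Beta shape parameters (default 8, 2).
#' @param coverage_lambda Mean per-CpG read coverage (default 30).
#' @param conv_fail Probability an unmethylated C reads as methylated
#'   (default 0.004).
#' @param repeat_frac Fraction of each chromosome covered by the simulated
#'   repeat track (default 0.1).
#' @param hyper If `TRUE`, plant hypermethylation instead of the default
#'   hypomethylation.
#' @param seed Integer seed used when a generator is called stand-alone.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chroms = 2, chrom_len_bp = 1e6, cpg_spacing = 50,
                       n_celltypes = 2, n_dmrs = 100,
                       dmr_len_range = c(400, 1000), delta = 0.5,
                       beta_a = 8, beta_b = 2, coverage_lambda = 30,
                       conv_fail = 0.004, repeat_frac = 0.1, hyper = FALSE,
                       seed = 1) {
  stopifnot(n_chroms >= 1, chrom_len_bp > 0, cpg_spacing >= 1,
            n_celltypes >= 1, n_dmrs >= 0, length(dmr_len_range) == 2,
            dmr_len_range[1] > 0, dmr_len_range[2] >= dmr_len_range[1],
            delta >= 0, delta <= 1, beta_a > 0, beta_b > 0,
            coverage_lambda >= 0, conv_fail >= 0, conv_fail <= 0.05,
            repeat_frac >= 0, repeat_frac <= 1)
  structure(list(n_chroms = n_chroms, chrom_len_bp = chrom_len_bp,
                 cpg_spacing = cpg_spacing, n_celltypes = n_celltypes,
                 n_dmrs = n_dmrs, dmr_len_range = dmr_len_range,
                 delta = delta, beta_a = beta_a, beta_b = beta_b,
                 coverage_lambda = coverage_lambda, conv_fail = conv_fail,
                 repeat_frac = repeat_frac, hyper = hyper, seed = seed),
            class = "sim_config")
}

celltype_names <- function(config) sprintf("ct%02d", seq_len(config$n_celltypes))

#' Simulate CpG positions and a repeat track
#'
#' CpG positions follow geometric inter-CpG gaps with the configured mean
#' spacing. The repeat track marks a `repeat_frac` share of fixed 2-kb
#' blocks on each chromosome. Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @param seed Seed; `NULL` to use the ambient RNG stream.
#' @return List with `cpgs` (data.frame `chrom`, `pos`) and `repeats`
#'   (interval data.frame).
#' @export
simulate_genome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  cpgs <- list(); reps <- list()
  block <- 2000
  for (ch in chroms) {
    n_exp <- ceiling(config$chrom_len_bp / config$cpg_spacing * 1.3) + 50
    gaps <- stats::rgeom(n_exp, prob = 1 / config$cpg_spacing) + 1
    pos <- cumsum(gaps)
    pos <- pos[pos < config$chrom_len_bp]
    cpgs[[ch]] <- data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
    n_blocks <- floor(config$chrom_len_bp / block)
    if (config$repeat_frac > 0 && n_blocks > 0) {
      is_rep <- stats::runif(n_blocks) < config$repeat_frac
      if (any(is_rep)) {
        k <- which(is_rep) - 1
        reps[[ch]] <- data.frame(chrom = ch, start = k * block,
                                 end = (k + 1) * block, name = NA_character_,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  repeats <- if (length(reps)) do.call(rbind, reps)
             else genomic_intervals(character(0), numeric(0), numeric(0))
  rownames(repeats) <- NULL
  list(cpgs = do.call(rbind, cpgs), repeats = repeats)
}

#' Simulate true multi-cell-type methylomes with planted DMRs
#'
#' Draws a per-CpG baseline methylation level from Beta(a, b), shared by
#' all cell types, then places `n_dmrs` non-overlapping intervals; inside
#' each, a random non-empty subset of cell types has its methylation
#' reduced by `delta` (floored at 0; or raised and capped at 1 in hyper
#' mode).
#'
#' @param config A [sim_config()].
#' @param cpgs Data.frame of CpG positions from [simulate_genome()].
#' @param seed Seed; `NULL` to use the ambient RNG stream.
#' @return A `sim_truth` list: `levels` (CpG x cell-type matrix of true
#'   levels), `cpgs`, `dmrs` (interval data.frame with `affected` comma
#'   lists and `delta`), `config`.
#' @export
simulate_methylomes <- function(config, cpgs, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  cts <- celltype_names(config)
  base <- stats::rbeta(nrow(cpgs), config$beta_a, config$beta_b)
  levels <- matrix(base, nrow(cpgs), length(cts), dimnames = list(NULL, cts))
  dmrs <- place_dmrs(config)
  if (nrow(dmrs)) {
    for (i in seq_len(nrow(dmrs))) {
      aff <- strsplit(dmrs$affected[i], ",", fixed = TRUE)[[1]]
      in_dmr <- cpgs$chrom == dmrs$chrom[i] &
        cpgs$pos >= dmrs$start[i] & cpgs$pos < dmrs$end[i]
      if (config$hyper)
        levels[in_dmr, aff] <- pmin(1, levels[in_dmr, aff] + config$delta)
      else
        levels[in_dmr, aff] <- pmax(0, levels[in_dmr, aff] - config$delta)
    }
  }
  structure(list(levels = levels, cpgs = cpgs, dmrs = dmrs, config = config),
            class = "sim_truth")
}

## Place n_dmrs non-overlapping intervals across the genome (rejection
## sampling per chromosome); error when the genome cannot hold them.
place_dmrs <- function(config) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      affected = character(0), delta = numeric(0),
                      stringsAsFactors = FALSE)
  if (config$n_dmrs == 0) return(empty)
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  need <- config$n_dmrs * mean(config$dmr_len_range) * 2
  if (need > config$n_chroms * config$chrom_len_bp)
    stop("genome too small for ", config$n_dmrs, " planted DMRs")
  cts <- celltype_names(config)
  per <- diff(c(0, round(seq_len(config$n_chroms) / config$n_chroms *
                           config$n_dmrs)))
  out <- list()
  for (ci in seq_along(chroms)) {
    k <- per[ci]
    if (k == 0) next
    placed <- data.frame(start = numeric(0), end = numeric(0))
    tries <- 0
    while (nrow(placed) < k) {
      tries <- tries + 1
      if (tries > 2000 * k) stop("could not place non-overlapping DMRs")
      len <- round(stats::runif(1, config$dmr_len_range[1],
                                config$dmr_len_range[2]))
      s <- floor(stats::runif(1, 0, config$chrom_len_bp - len))
      if (!any(s < placed$end & placed$start < s + len))
        placed <- rbind(placed, data.frame(start = s, end = s + len))
    }
    placed <- placed[order(placed$start), , drop = FALSE]
    aff <- vapply(seq_len(k), function(i) {
      sub <- cts[stats::runif(length(cts)) < 0.5]
      if (!length(sub)) sub <- sample(cts, 1)
      paste(sub, collapse = ",")
    }, "")
    out[[ci]] <- data.frame(chrom = chroms[ci], start = placed$start,
                            end = placed$end, name = NA_character_,
                            affected = aff, delta = config$delta,
                            stringsAsFactors = FALSE)
  }
  x <- do.call(rbind, out)
  x$name <- sprintf("dmr%04d", seq_len(nrow(x)))
  rownames(x) <- NULL
  x
}

#' Simulate observed CpG calls for one cell type
#'
#' Per CpG, total reads are Poisson(`coverage_lambda`) and methylated reads
#' are Binomial(total, `m + (1 - m) * conv_fail`) where `m` is the true
#' level — conversion failure makes a fraction of unmethylated cytosines
#' read as methylated. CpGs with zero reads are omitted.
#'
#' @param truth A `sim_truth` from [simulate_methylomes()].
#' @param celltype Cell-type id (a column of `truth$levels`).
#' @param seed Seed; `NULL` to use the ambient RNG stream.
#' @return A `cpg_calls` object.
#' @export
simulate_calls <- function(truth, celltype, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!celltype %in% colnames(truth$levels))
    stop("unknown cell type: ", celltype)
  if (!is.null(seed)) set.seed(seed)
  cfg <- truth$config
  n <- nrow(truth$cpgs)
  tot <- stats::rpois(n, cfg$coverage_lambda)
  m <- truth$levels[, celltype]
  p <- m + (1 - m) * cfg$conv_fail
  meth <- stats::rbinom(n, tot, p)
  keep <- tot > 0
  cpg_calls(truth$cpgs$chrom[keep], truth$cpgs$pos[keep],
            meth[keep], tot[keep], sample_id = celltype)
}

#' Simulate annotation tracks tied to the planted truth
#'
#' Generates an enhancer track overlapping a configurable fraction of the
#' planted DMRs (plus background intervals), a TSS list, and an eQTL track
#' overlapping a fraction of the DMRs.
#'
#' @param truth A `sim_truth`.
#' @param enhancer_overlap_frac Fraction of planted DMRs that get an
#'   overlapping enhancer (default 0.7).
#' @param eqtl_overlap_frac Fraction of planted DMRs that get an
#'   overlapping eQTL interval (default 0.3).
#' @param n_background Number of background intervals per track unrelated
#'   to the truth (default 50).
#' @param n_tss Number of TSS records (default 50).
#' @param seed Seed; `NULL` to use the ambient RNG stream.
#' @return List with `enhancers`, `promoters` (via [make_promoters()]),
#'   `tss`, `eqtls`.
#' @export
simulate_tracks <- function(truth, enhancer_overlap_frac = 0.7,
                            eqtl_overlap_frac = 0.3, n_background = 50,
                            n_tss = 50, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- truth$config
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  rand_iv <- function(n, len) {
    if (n == 0) return(genomic_intervals(character(0), numeric(0), numeric(0)))
    ch <- sample(chroms, n, replace = TRUE)
    s <- floor(stats::runif(n, 0, cfg$chrom_len_bp - len))
    genomic_intervals(ch, s, s + len)
  }
  on_dmrs <- function(frac, len) {
    if (nrow(truth$dmrs) == 0 || frac <= 0)
      return(genomic_intervals(character(0), numeric(0), numeric(0)))
    k <- round(frac * nrow(truth$dmrs))
    if (k == 0) return(genomic_intervals(character(0), numeric(0), numeric(0)))
    idx <- sort(sample(nrow(truth$dmrs), k))
    mid <- floor((truth$dmrs$start[idx] + truth$dmrs$end[idx]) / 2)
    genomic_intervals(truth$dmrs$chrom[idx], pmax(0, mid - floor(len / 2)),
                      mid + ceiling(len / 2))
  }
  enhancers <- sort_intervals(rbind(on_dmrs(enhancer_overlap_frac, 600),
                                    rand_iv(n_background, 600)))
  eqtls <- sort_intervals(rbind(on_dmrs(eqtl_overlap_frac, 200),
                                rand_iv(n_background, 200)))
  tss <- data.frame(chrom = sample(chroms, n_tss, replace = TRUE),
                    pos = floor(stats::runif(n_tss, 1000,
                                             cfg$chrom_len_bp - 1000)),
                    name = sprintf("gene%03d", seq_len(n_tss)),
                    strand = sample(c("+", "-"), n_tss, replace = TRUE),
                    stringsAsFactors = FALSE)
  rownames(enhancers) <- rownames(eqtls) <- NULL
  list(enhancers = enhancers, promoters = make_promoters(tss), tss = tss,
       eqtls = eqtls)
}

#' Build a candidate-region set from the simulation truth
#'
#' Converts the planted DMRs (plus static decoy regions) into the
#' candidate-set input of the panel designer, using the true methylation
#' levels: per-region sample means, per-CpG levels, and the repeat-masked
#' fraction against the simulated repeat track.
#'
#' @param truth A `sim_truth`.
#' @param repeats Repeat track from [simulate_genome()].
#' @param n_decoys Number of static (non-DMR) candidate regions added
#'   (default 30).
#' @param seed Seed; `NULL` to use the ambient RNG stream.
#' @return A [candidate_set()].
#' @export
simulate_candidates <- function(truth, repeats, n_decoys = 30, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- truth$config
  iv <- truth$dmrs[, c("chrom", "start", "end", "name")]
  if (n_decoys > 0) {
    chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
    dec <- list(); got <- 0; tries <- 0
    while (got < n_decoys && tries < 200 * n_decoys) {
      tries <- tries + 1
      len <- round(stats::runif(1, cfg$dmr_len_range[1], cfg$dmr_len_range[2]))
      ch <- sample(chroms, 1)
      s <- floor(stats::runif(1, 0, cfg$chrom_len_bp - len))
      cand <- data.frame(chrom = ch, start = s, end = s + len,
                         name = sprintf("static%03d", got + 1))
      if (!nrow(truth$dmrs) ||
          !any(truth$dmrs$chrom == ch & s < truth$dmrs$end &
                 truth$dmrs$start < s + len)) {
        got <- got + 1
        dec[[got]] <- cand
      }
    }
    iv <- rbind(iv, do.call(rbind, dec))
  }
  iv <- sort_intervals(iv)
  rownames(iv) <- NULL
  keep <- logical(nrow(iv))
  cpg_levels <- vector("list", nrow(iv))
  sample_levels <- matrix(NA_real_, nrow(iv), ncol(truth$levels),
                          dimnames = list(iv$name, colnames(truth$levels)))
  for (i in seq_len(nrow(iv))) {
    in_r <- truth$cpgs$chrom == iv$chrom[i] &
      truth$cpgs$pos >= iv$start[i] & truth$cpgs$pos < iv$end[i]
    if (!any(in_r)) next
    keep[i] <- TRUE
    cpg_levels[[i]] <- truth$levels[in_r, , drop = FALSE]
    sample_levels[i, ] <- colMeans(truth$levels[in_r, , drop = FALSE])
  }
  iv2 <- iv[keep, , drop = FALSE]
  rf <- repeat_fraction(iv2, repeats)
  candidate_set(iv2, sample_levels[keep, , drop = FALSE], cpg_levels[keep],
                rf, source = "sim")
}

#' Repeat-masked fraction of each region
#'
#' @param regions Interval data.frame.
#' @param repeats Repeat track (intervals may overlap; they are merged
#'   first).
#' @return Numeric vector of per-region repeat-covered base fractions.
#' @export
repeat_fraction <- function(regions, repeats) {
  validate_intervals(regions, "regions")
  validate_intervals(repeats, "repeats")
  out <- numeric(nrow(regions))
  if (nrow(repeats) == 0 || nrow(regions) == 0) return(out)
  rep_m <- merge_intervals(repeats)$intervals
  h <- interval_hits(regions, rep_m)
  if (nrow(h)) {
    ov <- pmin(regions$end[h$query], rep_m$end[h$subject]) -
      pmax(regions$start[h$query], rep_m$start[h$subject])
    agg <- tapply(ov, h$query, sum)
    idx <- as.integer(names(agg))
    out[idx] <- as.numeric(agg) / (regions$end[idx] - regions$start[idx])
  }
  out
}

#' Run the full synthetic experiment
#'
#' Convenience wrapper: one seeded random stream drives genome, methylome,
#' per-cell-type calls, annotation tracks and the candidate set.
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` when given.
#' @return List with `truth`, `cpgs`, `repeats`, `callsets` (named list of
#'   `cpg_calls`), `tracks`, `candidates`.
#' @export
simulate_experiment <- function(config = sim_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  g <- simulate_genome(config, seed = NULL)
  truth <- simulate_methylomes(config, g$cpgs, seed = NULL)
  callsets <- lapply(celltype_names(config), function(ct)
    simulate_calls(truth, ct, seed = NULL))
  names(callsets) <- celltype_names(config)
  tracks <- simulate_tracks(truth, seed = NULL)
  cands <- simulate_candidates(truth, g$repeats, seed = NULL)
  list(truth = truth, cpgs = g$cpgs, repeats = g$repeats,
       callsets = callsets, tracks = tracks, candidates = cands)
}

#' Tile-level truth labels for a pair of cell types
#'
#' Labels each tile as truly dynamic when the absolute difference of the
#' true mean methylation (averaged over the tile's CpGs) between the two
#' cell types is at least `delta_min`. This is the ground truth against
#' which tile-level DMR calls are scored.
#'
#' @param tiles Interval data.frame of tiles.
#' @param truth A `sim_truth`.
#' @param pair Character vector of two cell-type ids.
#' @param delta_min Minimum true difference to count as dynamic
#'   (default 0.3).
#' @return Logical vector, one entry per tile (`NA` for tiles without
#'   CpGs).
#' @export
planted_tile_truth <- function(tiles, truth, pair, delta_min = 0.3) {
  stopifnot(inherits(truth, "sim_truth"), length(pair) == 2,
            all(pair %in% colnames(truth$levels)))
  pts <- data.frame(chrom = truth$cpgs$chrom, start = truth$cpgs$pos,
                    end = truth$cpgs$pos + 1)
  h <- interval_hits(pts, tiles)
  out <- rep(NA, nrow(tiles))
  if (nrow(h)) {
    f <- factor(h$subject, levels = seq_len(nrow(tiles)))
    m1 <- tapply(truth$levels[h$query, pair[1]], f, mean)
    m2 <- tapply(truth$levels[h$query, pair[2]], f, mean)
    diffs <- abs(as.numeric(m1) - as.numeric(m2))
    out[!is.na(diffs)] <- diffs[!is.na(diffs)] >= delta_min
  }
  out
}

#' Tile-level sensitivity and precision of a DMR analysis
#'
#' Compares the significant tiles of a pairwise comparison against the
#' planted truth: sensitivity is the fraction of truly dynamic retained
#' tiles called significant; precision is the fraction of called tiles
#' that are truly dynamic. Only retained tiles with CpGs enter either
#' denominator.
#'
#' @param tm A coverage-filtered `tile_matrix`.
#' @param truth A `sim_truth`.
#' @param pair Character vector of two cell-type ids.
#' @param q_max,delta_min,delta_strict Significance thresholds as in
#'   [call_pairwise_dmrs()].
#' @param truth_delta Minimum true difference defining a dynamic tile
#'   (defaults to `delta_min`).
#' @return List with `sensitivity`, `precision`, `n_true`, `n_called`.
#' @export
recovery_stats <- function(tm, truth, pair, q_max = 0.05, delta_min = 0.3,
                           delta_strict = FALSE, truth_delta = delta_min) {
  stopifnot(inherits(tm, "tile_matrix"))
  lab <- planted_tile_truth(tm$tiles, truth, pair, delta_min = truth_delta)
  tests <- pairwise_tile_tests(tm, pair)
  dmeets <- if (delta_strict) abs(tests$delta) > delta_min
            else abs(tests$delta) >= delta_min
  called <- rep(FALSE, nrow(tm$tiles))
  called[tests$tile[tests$q_value <= q_max & dmeets]] <- TRUE
  eval_ok <- tm$retained & !is.na(lab)
  tp <- sum(called & lab & eval_ok)
  list(sensitivity = tp / sum(lab & eval_ok),
       precision = tp / sum(called & eval_ok),
       n_true = sum(lab & eval_ok), n_called = sum(called & eval_ok))
}
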