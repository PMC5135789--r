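#' Construct a candidate-region set for panel design
#'
#' A candidate set bundles the regions of one origin DMR collection with
#' everything the design procedure needs: per-sample mean methylation
#' levels, per-CpG methylation levels, and repeat-masked fraction.
#'
#' @param intervals Interval data.frame (`chrom`, `start`, `end`, `name`);
#'   `name` must contain unique region ids.
#' @param sample_levels Numeric matrix, regions x samples, of mean
#'   methylation levels in \[0, 1\]; rownames must match region ids.
#' @param cpg_levels List (one element per region, names = region ids) of
#'   numeric matrices CpGs x samples of per-CpG levels in \[0, 1\].
#' @param repeat_frac Numeric vector of repeat-masked base fractions in
#'   \[0, 1\], one per region.
#' @param source Label of the origin DMR collection.
#' @return A `candidate_set` list.
#' @export
candidate_set <- function(intervals, sample_levels, cpg_levels, repeat_frac,
                          source = "candidates") {
  validate_intervals(intervals, "candidates")
  if (anyDuplicated(intervals$name) || any(is.na(intervals$name)))
    stop("candidate_set: intervals$name must be unique region ids")
  n <- nrow(intervals)
  sample_levels <- as.matrix(sample_levels)
  stopifnot(nrow(sample_levels) == n, length(cpg_levels) == n,
            length(repeat_frac) == n)
  if (is.null(colnames(sample_levels)))
    stop("candidate_set: sample_levels needs sample-id column names")
  if (any(sample_levels < 0 | sample_levels > 1, na.rm = TRUE))
    stop("candidate_set: sample levels must lie in [0, 1]")
  if (any(repeat_frac < 0 | repeat_frac > 1))
    stop("candidate_set: repeat_frac must lie in [0, 1]")
  if (any(vapply(cpg_levels, nrow, 1L) < 1))
    stop("candidate_set: every region needs >= 1 CpG")
  rownames(sample_levels) <- intervals$name
  names(cpg_levels) <- intervals$name
  structure(list(intervals = intervals, sample_levels = sample_levels,
                 cpg_levels = cpg_levels, repeat_frac = repeat_frac,
                 source = source),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate set '", x$source, "': ", nrow(x$intervals), " regions, ",
      ncol(x$sample_levels), " samples\n", sep = "")
  invisible(x)
}

#' Panel-design configuration
#'
#' Thresholds of the candidate filter and selection procedure, with the
#' standard defaults: dynamic CpGs at a minimum pairwise methylation
#' difference of 0.3, repeat content at most 0.6, at least 2 dynamic CpGs,
#' minimum region length 100 bp, sex chromosomes excluded.
#'
#' @param diff_threshold Minimum per-CpG methylation difference for a CpG
#'   to count as dynamic (default 0.3).
#' @param repeat_max Maximum repeat-masked fraction (default 0.6).
#' @param repeat_inclusive Use `<=` (default) rather than `<` at the bound.
#' @param min_dynamic_cpgs Minimum dynamic CpGs per region (default 2).
#' @param min_length_bp Minimum region length (default 100).
#' @param budget_bp Selection budget per source set in bp (default 5e7).
#' @param exclude_chroms Chromosomes removed before design (default the sex
#'   chromosomes).
#' @return A `design_config` list.
#' @export
design_config <- function(diff_threshold = 0.3, repeat_max = 0.6,
                          repeat_inclusive = TRUE, min_dynamic_cpgs = 2,
                          min_length_bp = 100, budget_bp = 5e7,
                          exclude_chroms = c("chrX", "chrY")) {
  stopifnot(diff_threshold >= 0, diff_threshold <= 1,
            repeat_max >= 0, repeat_max <= 1,
            min_dynamic_cpgs >= 0, min_length_bp >= 0, budget_bp > 0)
  structure(list(diff_threshold = diff_threshold, repeat_max = repeat_max,
                 repeat_inclusive = repeat_inclusive,
                 min_dynamic_cpgs = min_dynamic_cpgs,
                 min_length_bp = min_length_bp, budget_bp = budget_bp,
                 exclude_chroms = exclude_chroms),
            class = "design_config")
}

#' Count dynamic CpGs in a region
#'
#' A CpG is dynamic when its methylation level differs by at least
#' `diff_threshold` between some pair of samples, i.e. when
#' `max - min >= diff_threshold` across samples.
#'
#' @param cpg_mat Numeric matrix CpGs x samples of per-CpG levels.
#' @param diff_threshold Minimum difference (default 0.3, inclusive).
#' @return Integer count.
#' @export
dynamic_cpg_count <- function(cpg_mat, diff_threshold = 0.3) {
  cpg_mat <- as.matrix(cpg_mat)
  if (ncol(cpg_mat) < 2)
    stop("dynamic_cpg_count: need >= 2 samples for a pairwise difference")
  rng <- apply(cpg_mat, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2) 0 else max(r) - min(r)
  })
  sum(rng >= diff_threshold)
}

#' Filter candidate regions for capture suitability
#'
#' Retains regions that satisfy all of: repeat fraction within the bound,
#' at least `min_dynamic_cpgs` dynamic CpGs, length at least
#' `min_length_bp`, and chromosome not excluded. Input order is preserved;
#' the filter is idempotent.
#'
#' @param cands A [candidate_set()].
#' @param config A [design_config()].
#' @return The filtered `candidate_set`.
#' @export
filter_candidates <- function(cands, config = design_config()) {
  stopifnot(inherits(cands, "candidate_set"))
  iv <- cands$intervals
  rep_ok <- if (config$repeat_inclusive) cands$repeat_frac <= config$repeat_max
            else cands$repeat_frac < config$repeat_max
  dyn <- vapply(cands$cpg_levels, dynamic_cpg_count, 1L,
                diff_threshold = config$diff_threshold)
  keep <- rep_ok &
    dyn >= config$min_dynamic_cpgs &
    (iv$end - iv$start) >= config$min_length_bp &
    !(iv$chrom %in% config$exclude_chroms)
  subset_candidates(cands, which(keep))
}

subset_candidates <- function(cands, idx) {
  structure(list(intervals = cands$intervals[idx, , drop = FALSE],
                 sample_levels = cands$sample_levels[idx, , drop = FALSE],
                 cpg_levels = cands$cpg_levels[idx],
                 repeat_frac = cands$repeat_frac[idx],
                 source = cands$source),
            class = "candidate_set")
}

#' Score candidate regions for panel selection
#'
#' Computes the three-component region score: (1) density of dynamic CpGs
#' (count per bp), (2) maximum pairwise difference of region-mean
#' methylation across samples, (3) a 0/1 flag for overlap (>= 1 shared
#' base) with a putative enhancer or promoter. Each component is min-max
#' rescaled to the unit interval across the input set and the three are
#' added, giving a score in \[0, 3\]; a component constant across the set
#' rescales to 0 for every region (it carries no rank information). The
#' origin of each region — the sample with minimal mean methylation — is
#' recorded alongside.
#'
#' @param cands A filtered [candidate_set()].
#' @param enhancer_track,promoter_track Interval data.frames (either may be
#'   empty).
#' @param diff_threshold Dynamic-CpG difference threshold (default 0.3).
#' @return A `scored_regions` data.frame sorted by decreasing score, with
#'   columns `region_id`, `chrom`, `start`, `end`, `length`, `source`,
#'   `n_dynamic_cpgs`, `density`, `max_diff`, `overlap_flag`, rescaled
#'   component columns, `score` and `origin`.
#' @export
score_regions <- function(cands, enhancer_track = NULL, promoter_track = NULL,
                          diff_threshold = 0.3) {
  stopifnot(inherits(cands, "candidate_set"))
  iv <- cands$intervals
  if (nrow(iv) == 0) stop("score_regions: empty candidate set")
  empty <- genomic_intervals(character(0), numeric(0), numeric(0))
  if (is.null(enhancer_track)) enhancer_track <- empty
  if (is.null(promoter_track)) promoter_track <- empty
  dyn <- vapply(cands$cpg_levels, dynamic_cpg_count, 1L,
                diff_threshold = diff_threshold)
  len <- iv$end - iv$start
  max_diff <- apply(cands$sample_levels, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2) 0 else max(r) - min(r)
  })
  flag <- as.numeric(overlaps_any_vec(iv, enhancer_track) |
                       overlaps_any_vec(iv, promoter_track))
  rescale <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1]) / diff(rng)
  }
  out <- data.frame(region_id = iv$name, chrom = iv$chrom, start = iv$start,
                    end = iv$end, length = len, source = cands$source,
                    n_dynamic_cpgs = dyn, density = dyn / len,
                    max_diff = max_diff, overlap_flag = flag,
                    stringsAsFactors = FALSE)
  out$density_scaled <- rescale(out$density)
  out$max_diff_scaled <- rescale(out$max_diff)
  out$overlap_scaled <- rescale(out$overlap_flag)
  out$score <- out$density_scaled + out$max_diff_scaled + out$overlap_scaled
  out$origin <- apply(cands$sample_levels, 1, assign_origin_row)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scored_regions", "data.frame")
  out
}

## argmin sample id of a named level vector; ties -> lexicographically first
assign_origin_row <- function(levels) {
  levels <- levels[!is.na(levels)]
  min(names(levels)[levels == min(levels)])
}

#' Origin cell type of a candidate region
#'
#' The sample with the minimal region-mean methylation level — the cell
#' type in which the region is most hypomethylated, taken as the region's
#' origin for balanced selection. Ties resolve to the lexicographically
#' smallest sample id.
#'
#' @param sample_levels Named numeric vector of region-mean levels, or a
#'   [candidate_set()] (then a vector of origins, one per region, is
#'   returned).
#' @return Sample id(s).
#' @export
assign_origin <- function(sample_levels) {
  if (inherits(sample_levels, "candidate_set"))
    return(apply(sample_levels$sample_levels, 1, assign_origin_row))
  assign_origin_row(sample_levels)
}

#' Balanced greedy selection of scored regions under a byte budget
#'
#' Selects regions in decreasing score while keeping the origins (most
#' hypomethylated cell types) evenly represented: at every step the origin
#' with the smallest cumulative selected bp that still has candidates left
#' contributes its highest-scored remaining region (ties between origins
#' resolve lexicographically). This deliberately skips higher-scored
#' regions whose origin is already over-represented. Selection stops once
#' the total reaches the budget — the budget-crossing region is kept — or
#' the candidates are exhausted.
#'
#' @param scored A `scored_regions` data.frame (sorted by decreasing
#'   score).
#' @param budget_bp Positive selection budget in bp.
#' @return A `panel_selection` list: `selected` (rows of `scored` in
#'   selection order), `remaining` (unselected rows, rank order preserved),
#'   `total_bp`, `origin_bp` (named cumulative bp per origin).
#' @export
balanced_select <- function(scored, budget_bp) {
  stopifnot(inherits(scored, "scored_regions"))
  if (budget_bp <= 0) stop("balanced_select: budget_bp must be > 0")
  scored <- scored[order(-scored$score), , drop = FALSE]
  origins <- sort(unique(scored$origin))
  cum <- stats::setNames(numeric(length(origins)), origins)
  taken <- logical(nrow(scored))
  order_taken <- integer(0)
  total <- 0
  while (total < budget_bp && !all(taken)) {
    open <- origins[origins %in% scored$origin[!taken]]
    o <- open[which.min(cum[open])]   # which.min: first (lexicographic) tie-break
    i <- which(!taken & scored$origin == o)[1]  # best remaining of that origin
    taken[i] <- TRUE
    order_taken <- c(order_taken, i)
    cum[o] <- cum[o] + scored$length[i]
    total <- total + scored$length[i]
  }
  structure(list(selected = scored[order_taken, , drop = FALSE],
                 remaining = scored[!taken, , drop = FALSE],
                 total_bp = total, origin_bp = cum),
            class = "panel_selection")
}

#' @export
print.panel_selection <- function(x, ...) {
  cat("Panel selection: ", nrow(x$selected), " regions, ", x$total_bp,
      " bp across ", length(x$origin_bp), " origins\n", sep = "")
  invisible(x)
}

#' Augment a selection with eQTL-overlapping regions
#'
#' From the unselected remainder of a ranked list, returns every region
#' that shares at least one base with an eQTL interval, preserving rank
#' order. Used to add cohort-relevant regions after the balanced budget is
#' spent.
#'
#' @param remaining A `scored_regions` data.frame (e.g. the `remaining`
#'   element of [balanced_select()]).
#' @param eqtl_track Interval data.frame of eQTL loci.
#' @return The overlapping subset, rank order preserved.
#' @export
eqtl_augment <- function(remaining, eqtl_track) {
  validate_intervals(eqtl_track, "eQTL track")
  hit <- overlaps_any_vec(remaining, eqtl_track)
  out <- remaining[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the final capture panel from selected region lists
#'
#' Takes the union of one or more interval lists, merges intervals sharing
#' at least one base (bookended regions stay separate), concatenates
#' provenance labels of merged members, and sorts the result.
#'
#' @param selections List of interval data.frames (each with `chrom`,
#'   `start`, `end` and optionally `source`); names of the list are used as
#'   provenance labels when a `source` column is absent.
#' @return A `meth_panel`: interval data.frame with `name` (provenance)
#'   plus attributes `total_bp` and `n_regions`.
#' @export
assemble_panel <- function(selections) {
  stopifnot(is.list(selections), length(selections) >= 1)
  labels <- names(selections)
  if (is.null(labels)) labels <- paste0("set", seq_along(selections))
  all <- do.call(rbind, lapply(seq_along(selections), function(i) {
    x <- as.data.frame(selections[[i]])
    validate_intervals(x, paste0("selection ", i))
    data.frame(chrom = x$chrom, start = x$start, end = x$end,
               source = if (!is.null(x$source)) as.character(x$source)
                        else labels[i],
               stringsAsFactors = FALSE)
  }))
  m <- merge_intervals(all)
  prov <- vapply(m$revmap, function(i)
    paste(sort(unique(all$source[i])), collapse = ","), "")
  panel <- m$intervals
  panel$name <- prov
  rownames(panel) <- NULL
  attr(panel, "total_bp") <- sum(panel$end - panel$start)
  attr(panel, "n_regions") <- nrow(panel)
  class(panel) <- c("meth_panel", "data.frame")
  panel
}

#' @export
print.meth_panel <- function(x, ...) {
  cat("Capture panel: ", nrow(x), " regions, ",
      format(sum(x$end - x$start), big.mark = ","), " bp\n", sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 5), ...)
  invisible(x)
}

#' Summarise a panel against annotation tracks
#'
#' Reports panel size, CpG content, and for each annotation track: how
#' many of its features the panel touches (>= 1 shared base), the fraction
#' of features touched, and the fraction of panel regions overlapping the
#' track.
#'
#' @param panel A `meth_panel` (or any interval data.frame).
#' @param tracks Named list of interval data.frames.
#' @param cpg_positions Optional data.frame (`chrom`, `pos`) of CpG
#'   positions to count inside the panel.
#' @return A list with scalars `n_regions`, `total_bp`, `n_cpgs` and a
#'   data.frame `tracks` (one row per track).
#' @export
panel_summary <- function(panel, tracks = list(), cpg_positions = NULL) {
  validate_intervals(panel, "panel")
  n_cpgs <- NA_integer_
  if (!is.null(cpg_positions) && nrow(panel)) {
    pts <- data.frame(chrom = cpg_positions$chrom,
                      start = cpg_positions$pos, end = cpg_positions$pos + 1)
    n_cpgs <- sum(overlaps_any_vec(pts, panel))
  } else if (!is.null(cpg_positions)) n_cpgs <- 0L
  tr <- do.call(rbind, lapply(names(tracks), function(nm) {
    t <- tracks[[nm]]
    validate_intervals(t, nm)
    feat_hit <- overlaps_any_vec(t, panel)
    panel_hit <- overlaps_any_vec(panel, t)
    data.frame(track = nm, n_features = nrow(t),
               n_features_covered = sum(feat_hit),
               pct_features_covered = if (nrow(t)) mean(feat_hit) else 0,
               pct_panel_overlapping = if (nrow(panel)) mean(panel_hit) else 0,
               stringsAsFactors = FALSE)
  }))
  if (is.null(tr))
    tr <- data.frame(track = character(0), n_features = integer(0),
                     n_features_covered = integer(0),
                     pct_features_covered = numeric(0),
                     pct_panel_overlapping = numeric(0))
  list(n_regions = nrow(panel), total_bp = sum(panel$end - panel$start),
       n_cpgs = n_cpgs, tracks = tr)
}
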