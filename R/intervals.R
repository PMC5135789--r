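#' Construct a validated set of genomic intervals
#'
#' Intervals use the BED convention throughout the package: 0-based,
#' half-open `[start, end)`. Two intervals overlap only if they share at
#' least one base; bookended intervals (`end == start` of the next) do not.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer vector of 0-based start offsets (`>= 0`).
#' @param end Integer vector of exclusive end offsets (`> start`).
#' @param name Optional character vector of labels (recycled `NA` if absent).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`.
#' @examples
#' genomic_intervals("chr1", 0, 100)
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_) {
  n <- max(length(chrom), length(start), length(end))
  x <- data.frame(chrom = rep_len(as.character(chrom), n),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  name = rep_len(as.character(name), n),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

#' Validate a genomic-interval data frame
#'
#' Checks the interval invariants: `end > start`, `start >= 0`, non-empty
#' chromosome names. Called by every operation that consumes intervals.
#'
#' @param x A data.frame with columns `chrom`, `start`, `end`.
#' @param what Label used in error messages.
#' @return Invisibly, `x`.
#' @export
validate_intervals <- function(x, what = "interval set") {
  stopifnot(is.data.frame(x))
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(x)))
    stop(what, ": missing column(s) ", paste(setdiff(req, names(x)), collapse = ", "))
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(!(x$end > x$start) | x$start < 0 | is.na(x$chrom) | x$chrom == "")
  if (length(bad))
    stop(what, ": invalid interval at row ", bad[1],
         " (need end > start >= 0 and non-empty chrom)")
  invisible(x)
}

## Sort intervals: chromosomes in natural order (chr1..chr22 numerically,
## then others lexicographically), positions ascending within chromosome.
sort_intervals <- function(x) {
  if (nrow(x) == 0) return(x)
  x[order(chrom_rank(x$chrom), x$start, x$end), , drop = FALSE]
}

## order-compatible sort key: chr1..chr22 numerically, then others
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.integer(sub("^chr", "", chrom)))
  ifelse(is.na(num), paste0("z", chrom), sprintf("a%05d", num))
}

## Internal: IRanges view of a 0-based half-open interval frame (1-based closed)
.ir <- function(x) IRanges::IRanges(start = as.integer(x$start) + 1L,
                                    end = as.integer(x$end))

## Internal: all overlap pairs (>= 1 shared base) between two interval frames.
## Returns data.frame(query, subject) of row indices.
interval_hits <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0)
    return(data.frame(query = integer(0), subject = integer(0)))
  res <- vector("list", 0)
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    h <- IRanges::findOverlaps(.ir(query[qi, , drop = FALSE]),
                               .ir(subject[si, , drop = FALSE]))
    res[[length(res) + 1L]] <- data.frame(query = qi[S4Vectors::queryHits(h)],
                                          subject = si[S4Vectors::subjectHits(h)])
  }
  if (!length(res)) return(data.frame(query = integer(0), subject = integer(0)))
  do.call(rbind, res)
}

#' Base-pair overlap between two intervals
#'
#' @param a,b Single-row interval data.frames (or lists) with `chrom`,
#'   `start`, `end`.
#' @return `max(0, min(end) - max(start))` if on the same chromosome, else 0.
#' @examples
#' overlap_bp(genomic_intervals("chr1", 0, 100), genomic_intervals("chr1", 50, 150))
#' @export
overlap_bp <- function(a, b) {
  if (a$chrom[1] != b$chrom[1]) return(0)
  max(0, min(a$end[1], b$end[1]) - max(a$start[1], b$start[1]))
}

#' Does a region share at least one base with any interval of a track?
#'
#' The overlap rule used for all feature annotation in the package: a region
#' counts as overlapping a track if it shares >= 1 base with any of the
#' track's intervals. Bookended intervals do not overlap.
#'
#' @param region Single-row interval data.frame.
#' @param track Interval data.frame (an annotation track).
#' @return Logical scalar.
#' @export
overlaps_any <- function(region, track) {
  validate_intervals(track, "track")
  any(overlaps_any_vec(region, track))
}

## Vectorised: for each row of `regions`, TRUE iff >= 1 bp overlap with track
overlaps_any_vec <- function(regions, track) {
  out <- logical(nrow(regions))
  h <- interval_hits(regions, track)
  out[unique(h$query)] <- TRUE
  out
}

## Merge intervals that share >= 1 base (bookends kept separate).
## Returns merged frame plus a `revmap` list of contributing input rows.
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0)
    return(list(intervals = x[, c("chrom", "start", "end")], revmap = list()))
  pieces <- list(); maps <- list()
  for (ch in unique(x$chrom)) {
    idx <- which(x$chrom == ch)
    red <- IRanges::reduce(.ir(x[idx, , drop = FALSE]),
                           min.gapwidth = 0L, with.revmap = TRUE)
    pieces[[ch]] <- data.frame(chrom = ch,
                               start = IRanges::start(red) - 1L,
                               end = IRanges::end(red),
                               stringsAsFactors = FALSE)
    maps[[ch]] <- lapply(S4Vectors::mcols(red)$revmap, function(i) idx[i])
  }
  out <- do.call(rbind, pieces)
  revmap <- do.call(c, unname(maps))
  o <- order(chrom_rank(out$chrom), out$start)
  rownames(out) <- NULL
  list(intervals = out[o, , drop = FALSE], revmap = revmap[o])
}

## Distance (bp) from each query interval to its nearest subject interval on
## the same chromosome; 0 if overlapping, Inf if no subject on that chromosome.
nearest_distance <- function(query, subject) {
  d <- rep(Inf, nrow(query))
  if (nrow(subject) == 0 || nrow(query) == 0) return(d)
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    hit <- IRanges::distanceToNearest(.ir(query[qi, , drop = FALSE]),
                                      .ir(subject[si, , drop = FALSE]))
    d[qi[S4Vectors::queryHits(hit)]] <- S4Vectors::mcols(hit)$distance
  }
  d
}
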