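#' Read a CpG methylation call table
#'
#' Reads the tab-separated per-sample CpG call format consumed by the whole
#' pipeline: columns `chrom`, `pos` (0-based position of the CpG's cytosine),
#' `meth_reads`, `total_reads`, with an optional `#`-prefixed header line and
#' an optional fifth `level` column (ignored on input; the level is always
#' recomputed from the counts). Records below the coverage cutoff are
#' dropped; the result is sorted by (chromosome, position).
#'
#' Callers that emit separate records for the two strands of a CpG
#' dinucleotide (positions `p` and `p + 1`) can be accommodated with
#' `collapse_strands = TRUE`, which sums the counts of such adjacent pairs
#' onto the lower position.
#'
#' @param path Path to the call table.
#' @param min_coverage Minimum `total_reads` to retain a CpG (default 1).
#' @param sample_id Sample label; defaults to the file base name.
#' @param collapse_strands Sum records at `pos` and `pos + 1` into one CpG.
#' @return A `cpg_calls` data.frame with columns `chrom`, `pos`,
#'   `meth_reads`, `total_reads`, `level` and attribute `sample_id`.
#' @export
read_cpg_calls <- function(path, min_coverage = 1, sample_id = NULL,
                           collapse_strands = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(cpg_calls(character(0), numeric(0), numeric(0), numeric(0),
                     sample_id = sample_id))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4))
    stop("malformed line ", lineno[which(nf < 4)[1]], " in ", path,
         ": expected >= 4 tab-separated fields")
  m <- matrix(unlist(lapply(parts, `[`, 1:4)), ncol = 4, byrow = TRUE)
  pos <- suppressWarnings(as.numeric(m[, 2]))
  meth <- suppressWarnings(as.numeric(m[, 3]))
  tot <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(pos) | is.na(meth) | is.na(tot))
  if (length(bad))
    stop("malformed line ", lineno[bad[1]], " in ", path,
         ": non-numeric pos/meth_reads/total_reads")
  viol <- which(meth > tot)
  if (length(viol))
    stop("validation error at line ", lineno[viol[1]], " in ", path,
         ": meth_reads > total_reads")
  x <- data.frame(chrom = m[, 1], pos = pos, meth_reads = meth,
                  total_reads = tot, stringsAsFactors = FALSE)
  if (collapse_strands) x <- collapse_cpg_strands(x)
  x <- x[x$total_reads >= min_coverage, , drop = FALSE]
  cpg_calls(x$chrom, x$pos, x$meth_reads, x$total_reads, sample_id = sample_id)
}

#' Construct a validated per-sample CpG call set
#'
#' @param chrom,pos,meth_reads,total_reads Parallel vectors, one entry per
#'   CpG. Positions are 0-based.
#' @param sample_id Sample label attached as an attribute.
#' @return A `cpg_calls` data.frame sorted by (chrom, pos), with `level`
#'   recomputed as `meth_reads / total_reads`.
#' @export
cpg_calls <- function(chrom, pos, meth_reads, total_reads, sample_id = "sample") {
  x <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                  meth_reads = as.numeric(meth_reads),
                  total_reads = as.numeric(total_reads),
                  stringsAsFactors = FALSE)
  if (nrow(x)) {
    if (any(x$total_reads < 1)) stop("cpg_calls: total_reads must be >= 1")
    if (any(x$meth_reads < 0 | x$meth_reads > x$total_reads))
      stop("cpg_calls: need 0 <= meth_reads <= total_reads")
    if (any(x$pos < 0)) stop("cpg_calls: pos must be >= 0")
    x <- x[order(chrom_rank(x$chrom), x$pos), , drop = FALSE]
    if (anyDuplicated(paste(x$chrom, x$pos)))
      stop("cpg_calls: duplicate (chrom, pos) record")
  }
  x$level <- if (nrow(x)) x$meth_reads / x$total_reads else numeric(0)
  rownames(x) <- NULL
  attr(x, "sample_id") <- sample_id
  class(x) <- c("cpg_calls", "data.frame")
  x
}

## Sum +/- strand records at pos and pos+1 onto the lower position.
collapse_cpg_strands <- function(x) {
  x <- x[order(chrom_rank(x$chrom), x$pos), , drop = FALSE]
  adj <- c(x$chrom[-1] == x$chrom[-nrow(x)] &
             x$pos[-1] == x$pos[-nrow(x)] + 1, FALSE)
  if (nrow(x) < 2 || !any(adj)) return(x)
  i <- which(adj)
  # avoid chaining: a position absorbed into its predecessor cannot absorb
  i <- i[c(TRUE, diff(i) > 1)]
  x$meth_reads[i] <- x$meth_reads[i] + x$meth_reads[i + 1]
  x$total_reads[i] <- x$total_reads[i] + x$total_reads[i + 1]
  x[-(i + 1), , drop = FALSE]
}

#' Write a CpG call table
#'
#' Deterministic, sorted, tab-separated output with a `#`-prefixed header;
#' round-trips exactly with [read_cpg_calls()].
#'
#' @param callset A `cpg_calls` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cpg_calls <- function(callset, path) {
  stopifnot(inherits(callset, "cpg_calls"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tpos\tmeth_reads\ttotal_reads\tlevel", con)
  if (nrow(callset))
    writeLines(sprintf("%s\t%d\t%d\t%d\t%.6g", callset$chrom,
                       as.integer(callset$pos), as.integer(callset$meth_reads),
                       as.integer(callset$total_reads), callset$level), con)
  invisible(path)
}

#' Read a BED interval track
#'
#' Accepts BED3+ (0-based, half-open); columns beyond the fourth are
#' ignored. Lines starting with `#`, `track` or `browser` are skipped.
#'
#' @param path Path to a BED file.
#' @param name Track label (default: file base name).
#' @return An interval data.frame (`chrom`, `start`, `end`, `name`) with
#'   attribute `track_name`.
#' @export
read_bed <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    x <- genomic_intervals(character(0), numeric(0), numeric(0))
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 3))
      stop("malformed line ", lineno[which(nf < 3)[1]], " in ", path,
           ": BED needs >= 3 fields")
    x <- data.frame(
      chrom = vapply(parts, `[`, "", 1),
      start = suppressWarnings(as.numeric(vapply(parts, `[`, "", 2))),
      end = suppressWarnings(as.numeric(vapply(parts, `[`, "", 3))),
      name = vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_, ""),
      stringsAsFactors = FALSE)
    bad <- which(is.na(x$start) | is.na(x$end))
    if (length(bad))
      stop("malformed line ", lineno[bad[1]], " in ", path, ": non-numeric coordinates")
    viol <- which(x$end <= x$start | x$start < 0)
    if (length(viol))
      stop("validation error at line ", lineno[viol[1]], " in ", path,
           ": need end > start >= 0")
  }
  x <- sort_intervals(x)
  rownames(x) <- NULL
  attr(x, "track_name") <- name
  x
}

#' Write an interval track as BED
#'
#' @param track Interval data.frame; optional `name` and `score` columns are
#'   written as BED columns 4-5 (with strand `.` as column 6 when a `strand`
#'   column is present).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(track, path) {
  validate_intervals(track, "track")
  track <- sort_intervals(track)
  cols <- list(track$chrom, as.integer(track$start), as.integer(track$end))
  if (!is.null(track$name) && any(!is.na(track$name))) {
    cols <- c(cols, list(ifelse(is.na(track$name), ".", track$name)))
    if (!is.null(track$score)) {
      cols <- c(cols, list(as.integer(round(track$score))))
      if (!is.null(track$strand)) cols <- c(cols, list(track$strand))
    }
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Global methylation level of a call set
#'
#' The coverage-weighted genome-wide methylation: summed methylated calls
#' over summed total calls across all CpGs. Algebraically identical to the
#' coverage-weighted mean of per-CpG levels.
#'
#' @param callset A `cpg_calls` object with >= 1 record.
#' @return Fraction in \[0, 1\].
#' @export
global_methylation <- function(callset) {
  stopifnot(inherits(callset, "cpg_calls"))
  if (nrow(callset) == 0)
    stop("global_methylation is undefined for an empty call set")
  sum(callset$meth_reads) / sum(callset$total_reads)
}

#' @export
print.cpg_calls <- function(x, ...) {
  cat("CpG call set: sample ", attr(x, "sample_id"), ", ",
      nrow(x), " CpGs", sep = "")
  if (nrow(x))
    cat(sprintf(", global methylation %.3f", global_methylation(x)))
  cat("\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 5), ...)
  invisible(x)
}
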