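#' Build promoter intervals from transcription start sites
#'
#' Promoters are defined as TSS +/- `flank_bp`, strand-independent, as the
#' symmetric window `[pos - flank, pos + flank)` clipped at zero.
#'
#' @param tss Data.frame with columns `chrom`, `pos` (0-based TSS) and
#'   optionally `name`, `strand`.
#' @param flank_bp Flank size in bp (default 1000).
#' @return Interval data.frame of promoter windows.
#' @export
make_promoters <- function(tss, flank_bp = 1000) {
  stopifnot(is.data.frame(tss), all(c("chrom", "pos") %in% names(tss)))
  if (nrow(tss) == 0)
    return(genomic_intervals(character(0), numeric(0), numeric(0)))
  if (any(tss$pos < 0)) stop("make_promoters: TSS positions must be >= 0")
  out <- genomic_intervals(tss$chrom, pmax(0, tss$pos - flank_bp),
                           tss$pos + flank_bp,
                           name = if (!is.null(tss$name)) tss$name else NA)
  sort_intervals(out)
}

#' Reciprocal overlap percentages between a panel and a feature track
#'
#' @param panel,track Interval data.frames.
#' @return Named numeric vector: `pct_track_covered` — fraction of track
#'   features sharing >= 1 base with any panel region — and
#'   `pct_panel_overlapping` — fraction of panel regions sharing >= 1 base
#'   with the track. Both in \[0, 1\]; 0 for empty inputs.
#' @export
feature_overlap_pct <- function(panel, track) {
  validate_intervals(panel, "panel")
  validate_intervals(track, "track")
  c(pct_track_covered =
      if (nrow(track)) mean(overlaps_any_vec(track, panel)) else 0,
    pct_panel_overlapping =
      if (nrow(panel)) mean(overlaps_any_vec(panel, track)) else 0)
}

#' Fraction of platform CpGs inside a panel
#'
#' A CpG is inside a panel region when its cytosine position lies in
#' `[start, end)`. Used to compare the CpG territory of other platforms
#' (bead arrays, RRBS, off-the-shelf capture) with a designed panel.
#'
#' @param platform_cpgs Data.frame with `chrom`, `pos` (0-based CpG
#'   positions).
#' @param panel Interval data.frame.
#' @return Fraction in \[0, 1\] (0 for an empty CpG list).
#' @export
platform_cpg_overlap <- function(platform_cpgs, panel) {
  stopifnot(is.data.frame(platform_cpgs),
            all(c("chrom", "pos") %in% names(platform_cpgs)))
  validate_intervals(panel, "panel")
  if (nrow(platform_cpgs) == 0) return(0)
  pts <- data.frame(chrom = platform_cpgs$chrom,
                    start = platform_cpgs$pos, end = platform_cpgs$pos + 1)
  mean(overlaps_any_vec(pts, panel))
}

#' Read a TSS list
#'
#' Accepts BED6 (TSS = interval start) or a 2+ column TSV with `chrom` and
#' `pos` columns (optional `#` header; extra columns `name`, `strand`).
#'
#' @param path Input path.
#' @return Data.frame with `chrom`, `pos`, `name`, `strand`.
#' @export
read_tss <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  # tolerate a plain header row (non-numeric position field)
  if (length(lines) &&
      is.na(suppressWarnings(as.numeric(strsplit(lines[1], "\t")[[1]][2]))))
    lines <- lines[-1]
  if (!length(lines))
    return(data.frame(chrom = character(0), pos = numeric(0),
                      name = character(0), strand = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i, default = NA_character_)
    vapply(parts, function(p) if (length(p) >= i) p[i] else default, "")
  data.frame(chrom = get(1), pos = as.numeric(get(2)), name = get(4),
             strand = get(6), stringsAsFactors = FALSE)
}
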