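#' Write a candidate set to a directory
#'
#' Emits the on-disk candidate format consumed by the panel designer:
#' `candidates.bed` (regions, name = region id), `sample_levels.tsv`
#' (region_id x sample matrix), `cpg_levels.tsv` (long table: region_id,
#' chrom, pos index, one level column per sample) and `repeat_frac.tsv`.
#'
#' @param cands A [candidate_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_candidates <- function(cands, dir) {
  stopifnot(inherits(cands, "candidate_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bed(cands$intervals, file.path(dir, "candidates.bed"))
  sl <- data.frame(region_id = rownames(cands$sample_levels),
                   cands$sample_levels, check.names = FALSE)
  utils::write.table(sl, file.path(dir, "sample_levels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  long <- do.call(rbind, lapply(names(cands$cpg_levels), function(id) {
    m <- cands$cpg_levels[[id]]
    data.frame(region_id = id, cpg_index = seq_len(nrow(m)), m,
               check.names = FALSE)
  }))
  utils::write.table(long, file.path(dir, "cpg_levels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(region_id = cands$intervals$name,
               repeat_frac = cands$repeat_frac),
    file.path(dir, "repeat_frac.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeLines(cands$source, file.path(dir, "source.txt"))
  invisible(dir)
}

#' Read a candidate set from a directory
#'
#' Counterpart of [write_candidates()]; round-trips a candidate set.
#'
#' @param dir Directory holding the candidate files.
#' @return A [candidate_set()].
#' @export
read_candidates <- function(dir) {
  need <- c("candidates.bed", "sample_levels.tsv", "cpg_levels.tsv",
            "repeat_frac.tsv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss))
    stop("candidate directory ", dir, " is missing: ",
         paste(miss, collapse = ", "))
  iv <- read_bed(file.path(dir, "candidates.bed"))
  sl <- utils::read.delim(file.path(dir, "sample_levels.tsv"),
                          check.names = FALSE)
  cl <- utils::read.delim(file.path(dir, "cpg_levels.tsv"),
                          check.names = FALSE)
  rf <- utils::read.delim(file.path(dir, "repeat_frac.tsv"))
  src_file <- file.path(dir, "source.txt")
  src <- if (file.exists(src_file)) readLines(src_file)[1] else basename(dir)
  samples <- setdiff(names(sl), "region_id")
  slm <- as.matrix(sl[, samples, drop = FALSE])
  rownames(slm) <- sl$region_id
  slm <- slm[match(iv$name, rownames(slm)), , drop = FALSE]
  cpg_levels <- lapply(iv$name, function(id) {
    as.matrix(cl[cl$region_id == id, samples, drop = FALSE])
  })
  rfv <- rf$repeat_frac[match(iv$name, rf$region_id)]
  candidate_set(iv, slm, cpg_levels, rfv, source = src)
}
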