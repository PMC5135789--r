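#' Parameters of the multi-sample Poisson coverage model
#'
#' Bundles the quantities needed to compute how much raw sequencing is
#' required so that each CpG reaches a target depth in a required fraction
#' of a cohort with a required probability. Per-base depth is modelled as
#' Poisson (Lander-Waterman); raw read counts are then inflated for PCR
#' duplicates and off-target reads.
#'
#' @param k Required depth per CpG (reads; default 30).
#' @param p_success Overall probability with which the requirement must hold
#'   (default 0.95).
#' @param sample_frac Fraction of the cohort in which each CpG must reach
#'   depth `k` (default 0.8).
#' @param n_samples Cohort size N.
#' @param target_bp Target territory L in bp (e.g. 9e7 for a 90-Mb capture
#'   design, 2.7e9 for whole-genome bisulfite sequencing).
#' @param read_len Read length in bp (default 100).
#' @param dup_rate Expected PCR-duplication rate in \[0, 1).
#' @param offtarget_rate Expected fraction of reads mapping outside the
#'   target territory, in \[0, 1).
#' @return A `coverage_model_params` list.
#' @export
coverage_model_params <- function(k = 30, p_success = 0.95, sample_frac = 0.8,
                                  n_samples = 1, target_bp, read_len = 100,
                                  dup_rate = 0, offtarget_rate = 0) {
  stopifnot(k >= 0, p_success > 0, p_success < 1,
            sample_frac > 0, sample_frac <= 1, n_samples >= 1,
            target_bp > 0, read_len > 0,
            dup_rate >= 0, dup_rate < 1, offtarget_rate >= 0, offtarget_rate < 1)
  structure(list(k = k, p_success = p_success, sample_frac = sample_frac,
                 n_samples = n_samples, target_bp = target_bp,
                 read_len = read_len, dup_rate = dup_rate,
                 offtarget_rate = offtarget_rate),
            class = "coverage_model_params")
}

#' Poisson upper-tail probability
#'
#' `P(X >= k)` for `X ~ Poisson(lam)`, the probability that a base is
#' covered by at least `k` reads at mean depth `lam`.
#'
#' @param k Required depth (non-negative integer).
#' @param lam Mean per-base depth (>= 0).
#' @return Probability in \[0, 1\].
#' @export
poisson_tail <- function(k, lam) {
  if (any(k < 0) || any(lam < 0)) stop("poisson_tail: k and lam must be >= 0")
  ifelse(k == 0, 1, stats::ppois(k - 1, lam, lower.tail = FALSE))
}

## Number of samples that must jointly succeed: ceil(f * N), guarded
## against floating-point noise in the product.
n_required_samples <- function(params) {
  as.integer(ceiling(params$sample_frac * params$n_samples - 1e-9))
}

#' Minimal mean depth meeting the multi-sample coverage requirement
#'
#' Finds by bisection the smallest Poisson rate `lambda` such that
#' `P(X >= k) ^ m >= p_success`, where `m = ceiling(sample_frac *
#' n_samples)` is the number of samples in which the CpG must reach depth
#' `k`. Sample captures are independent, so the joint probability over the
#' required samples is the m-th power of the single-sample tail.
#'
#' An alternative reading — at least `m` of the `N` samples succeed, with
#' the binomial over samples (`mode = "binomial"`) — is provided for
#' comparison; it yields smaller depth requirements than the joint-power
#' model used by default.
#'
#' @param params A [coverage_model_params()] object.
#' @param tol Absolute bisection tolerance on lambda (default 1e-6).
#' @param mode `"power"` (default) or `"binomial"`; see Details.
#' @return The minimal lambda (per-base mean depth), `>= 0`.
#' @export
min_lambda <- function(params, tol = 1e-6, mode = c("power", "binomial")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "coverage_model_params"))
  if (params$k == 0) return(0)
  m <- n_required_samples(params)
  ok <- function(lam) {
    pt <- poisson_tail(params$k, lam)
    if (mode == "power") pt^m >= params$p_success
    else stats::pbinom(m - 1, params$n_samples, pt, lower.tail = FALSE) >=
      params$p_success
  }
  lo <- 0
  hi <- max(2 * params$k, 10)
  while (!ok(hi)) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ok(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Raw reads per sample for a required mean depth
#'
#' Converts a per-base depth requirement into a raw per-sample read count:
#' `lambda * target_bp / read_len`, inflated by dividing by
#' `(1 - dup_rate) * (1 - offtarget_rate)` so that the surviving unique
#' on-target reads deliver the required depth.
#'
#' @param lambda_required Per-base mean depth (e.g. from [min_lambda()]).
#' @param params A [coverage_model_params()] object.
#' @return Raw reads required per sample.
#' @export
reads_required <- function(lambda_required, params) {
  stopifnot(inherits(params, "coverage_model_params"), lambda_required >= 0)
  lambda_required * params$target_bp / params$read_len /
    ((1 - params$dup_rate) * (1 - params$offtarget_rate))
}

#' Coverage-requirement curve over cohort sizes for two designs
#'
#' Computes, for every cohort size `N` in `n_range`, the minimal per-base
#' depth and the raw per-sample read count required under each of the
#' supplied parameter sets (typically a targeted capture design versus
#' whole-genome bisulfite sequencing).
#'
#' @param designs Named list of [coverage_model_params()] objects; the
#'   `n_samples` field of each is overridden by the curve's `N`.
#' @param n_range Integer vector of cohort sizes (default `1:100`).
#' @param tol Bisection tolerance passed to [min_lambda()].
#' @return A data.frame with columns `design`, `n_samples`, `lambda`,
#'   `reads`.
#' @export
coverage_curve <- function(designs, n_range = 1:100, tol = 1e-6) {
  stopifnot(is.list(designs), length(designs) >= 1)
  if (is.null(names(designs)) || any(!nzchar(names(designs))))
    names(designs) <- paste0("design", seq_along(designs))
  rows <- list()
  for (nm in names(designs)) {
    base <- designs[[nm]]
    for (N in n_range) {
      p <- base
      p$n_samples <- N
      lam <- min_lambda(p, tol = tol)
      rows[[length(rows) + 1L]] <-
        data.frame(design = nm, n_samples = N, lambda = lam,
                   reads = reads_required(lam, p), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.coverage_model_params <- function(x, ...) {
  cat(sprintf(paste0("Coverage model: depth >= %gx in ceil(%g x %d) samples ",
                     "with prob >= %g\n  target %g bp, reads %g bp, dup %g, ",
                     "off-target %g\n"),
              x$k, x$sample_frac, x$n_samples, x$p_success,
              x$target_bp, x$read_len, x$dup_rate, x$offtarget_rate))
  invisible(x)
}
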