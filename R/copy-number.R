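# Read-depth based copy-number estimation and carrier calling.

#' Coverage track over a region
#'
#' @param chrom chromosome id.
#' @param start,end region bounds, 0-based half-open (BED convention).
#' @param depth per-base depths, length `end - start`.
#' @param genome_mean genome-wide mean depth.
#' @return Object of class `coverage_track`.
#' @export
coverage_track <- function(chrom, start, end, depth, genome_mean) {
  if (end <= start) stop("empty region")
  if (length(depth) != end - start)
    stop("need one depth per base of the region")
  if (any(depth < 0)) stop("depths must be non-negative")
  structure(list(chrom = chrom, start = start, end = end,
                 depth = as.numeric(depth), genome_mean = genome_mean),
            class = "coverage_track")
}

#' Normalized coverage ratio of a region
#'
#' Mean regional depth divided by the genome-wide mean depth; a ratio near 0
#' is a deletion signature, near the copy number of the region otherwise.
#'
#' @param track a [coverage_track()].
#' @return Numeric ratio (>= 0).
#' @export
normalized_coverage <- function(track) {
  if (track$genome_mean <= 0) stop("genome-wide mean depth must be positive")
  mean(track$depth) / track$genome_mean
}

#' Call presence of a (non-reference) gene copy from coverage
#'
#' Carrier iff the mean depth over the region is at least `min_mean_depth`
#' (inclusive threshold; the default 5 reproduces the >= 5x carrier rule).
#'
#' @param track a [coverage_track()] on the non-reference assembly.
#' @param min_mean_depth inclusive carrier threshold (default 5).
#' @return Logical carrier flag.
#' @export
call_presence <- function(track, min_mean_depth = 5) {
  mean(track$depth) >= min_mean_depth
}

#' Integer copy number from a normalized coverage ratio
#'
#' `round(ratio * baseline)` with banker's rounding (ties to even).  For
#' multi-locus families the ratio is computed over the union of the
#' reference copies with the corresponding baseline (e.g. 2), so a ratio of
#' 1.5 over a 2-copy union gives 3 copies.
#'
#' @param ratio normalized coverage ratio.
#' @param baseline_copies copy number of the measured region in the
#'   reference (>= 1).
#' @return Integer copy number (>= 0).
#' @export
estimate_copies <- function(ratio, baseline_copies = 1) {
  stopifnot(baseline_copies >= 1, ratio >= 0)
  as.integer(round(ratio * baseline_copies))
}
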