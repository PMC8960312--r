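#' Genomic intervals (1-based, inclusive)
#'
#' Constructs a validated table of genomic intervals.  Coordinates follow
#' the convention used in clinical CNV reports: 1-based, both endpoints
#' included, so a call written `17p13.3 (1551800-2264023)x1` spans
#' `2264023 - 1551800 + 1 = 712224` bases.  Chromosome labels are
#' normalized by stripping a leading "chr" prefix (case-insensitive);
#' allowed labels are 1-22, X and Y.  BED input (0-based half-open) is
#' converted at the I/O boundary by [read_genes_bed()]; these constructors
#' always expect 1-based inclusive coordinates.
#'
#' @param chrom chromosome labels
#' @param start 1-based start positions (inclusive)
#' @param end 1-based end positions (inclusive); `end >= start`
#' @param build genome-build tag carried as free text (default "GRCh37");
#'   builds are never lifted over, and mixing builds within one panel is an
#'   error at panel construction
#' @return a `data.frame` of class `"gintv"` with columns
#'   `chrom`, `start`, `end`, `build`
#' @examples
#' gi <- gintv("17", 1551800, 2264023)
#' interval_length(gi)   # 712224
#' @export
gintv <- function(chrom, start, end, build = "GRCh37") {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(normalize_chrom(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  build <- rep_len(as.character(build), n)
  bad <- !is.finite(start) | !is.finite(end) | start < 1 | end < start |
    start != floor(start) | end != floor(end)
  if (any(bad)) {
    abort(sprintf(
      "invalid interval(s) at index %s: need 1 <= start <= end (integers)",
      paste(which(bad), collapse = ", ")))
  }
  structure(
    data.frame(chrom = chrom, start = start, end = end, build = build,
               stringsAsFactors = FALSE),
    class = c("gintv", "data.frame"))
}

as_gintv <- function(x) {
  if (inherits(x, "gintv")) return(x)
  gintv(x$chrom, x$start, x$end, x$build %||% "GRCh37")
}

#' Interval length in bases
#'
#' @param x a [gintv()] table (or any data.frame with `start`/`end`)
#' @return numeric vector of `end - start + 1`
#' @export
interval_length <- function(x) {
  x$end - x$start + 1
}

#' Base-pair overlap of two intervals
#'
#' Number of bases shared by `a` and `b` under 1-based inclusive
#' semantics; 0 when the chromosomes differ or the ranges are disjoint.
#' Adjacent-touching intervals such as 100-200 vs 200-300 share exactly
#' one base.  Vectorized with recycling; symmetric in its arguments and
#' bounded by the shorter interval's length.
#'
#' @param a,b [gintv()] tables (recycled to common length)
#' @return non-negative numeric vector
#' @export
overlap_bp <- function(a, b) {
  a <- as_gintv(a); b <- as_gintv(b)
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n)
  ib <- rep_len(seq_len(nrow(b)), n)
  ov <- pmin(a$end[ia], b$end[ib]) - pmax(a$start[ia], b$start[ib]) + 1
  ov[a$chrom[ia] != b$chrom[ib]] <- 0
  pmax(ov, 0)
}

#' Interval containment
#'
#' `TRUE` where `outer` completely contains `inner`: same chromosome,
#' `outer$start <= inner$start` and `inner$end <= outer$end`.  Every
#' interval contains itself.
#'
#' @param outer,inner [gintv()] tables (recycled to common length)
#' @return logical vector
#' @export
gi_contains <- function(outer, inner) {
  outer <- as_gintv(outer); inner <- as_gintv(inner)
  n <- max(nrow(outer), nrow(inner))
  io <- rep_len(seq_len(nrow(outer)), n)
  ii <- rep_len(seq_len(nrow(inner)), n)
  outer$chrom[io] == inner$chrom[ii] &
    outer$start[io] <= inner$start[ii] &
    inner$end[ii] <= outer$end[io]
}
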