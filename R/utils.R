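#' @keywords internal
"_PACKAGE"

# internal condition helper: all user-facing validation failures are
# "cnvconcord_error" so the CLI can map them to exit code 2
abort <- function(msg, class = "cnvconcord_error", ...) {
  stop(structure(
    class = c(class, "cnvconcord_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Round half up
#'
#' Rounds to `digits` decimal places with ties going away from zero toward
#' positive infinity (`0.5 -> 1`), the convention used for all printed
#' percentages in concordance reports (e.g. 177/234 is reported as 76%).
#' Base R's `round()` rounds half to even and would print 75% there... no,
#' it would not, but it does differ on exact halves such as 42.5.
#'
#' @param x numeric vector
#' @param digits integer, decimal places (default 0)
#' @return numeric vector
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5))        # 1 2 3
#' round_half_up(100 * 177 / 234)         # 76
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

#' Format a rate the way concordance reports print it
#'
#' Integer percent (round half up) followed by the exact fraction,
#' e.g. `"76% (177/234)"`.
#'
#' @param k numerator count
#' @param n denominator count
#' @return character scalar
#' @export
format_rate <- function(k, n) {
  sprintf("%d%% (%d/%d)", as.integer(round_half_up(100 * k / n)), k, n)
}

# strip "chr" prefix, uppercase X/Y, validate against 1-22/X/Y
normalize_chrom <- function(chrom) {
  c0 <- sub("^[Cc][Hh][Rr]", "", as.character(chrom))
  c0 <- toupper(c0)
  ok <- c0 %in% c(as.character(1:22), "X", "Y")
  if (!all(ok)) {
    abort(sprintf("invalid chromosome label(s): %s",
                  paste(unique(chrom[!ok]), collapse = ", ")))
  }
  c0
}

# %||% in the base-R spirit
`%||%` <- function(a, b) if (is.null(a)) b else a
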