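SIZE_BINS <- c("<1 Mb", "1-5 Mb", "5-10 Mb", ">10 Mb")

#' Size bin of a CNV length
#'
#' Bins used to describe CNV panel composition: `<1 Mb`, `1-5 Mb`,
#' `5-10 Mb`, `>10 Mb`.  Boundary convention (a choice; panel reports
#' print the bins without one): exactly 1 Mb falls in `1-5 Mb`, exactly
#' 5 Mb in `5-10 Mb`, exactly 10 Mb in `5-10 Mb`.
#'
#' @param length CNV length in bases (positive), or a `cnv_panel` /
#'   [gintv()] table whose lengths are taken via [interval_length()]
#' @return character vector of bin labels (levels in [size_bins()])
#' @export
size_class <- function(length) {
  if (is.data.frame(length)) length <- interval_length(length)
  if (any(!is.finite(length) | length <= 0)) {
    abort("CNV length must be positive")
  }
  ifelse(length < 1e6, SIZE_BINS[1],
    ifelse(length < 5e6, SIZE_BINS[2],
      ifelse(length <= 1e7, SIZE_BINS[3], SIZE_BINS[4])))
}

#' The four CNV size-bin labels, smallest to largest
#' @return character(4)
#' @export
size_bins <- function() SIZE_BINS

#' Construct a CNV call panel
#'
#' A panel is a validated data.frame of copy-number calls: one row per
#' loss (deletion) or gain (duplication/triplication) with a 1-based
#' inclusive interval, a genome-build tag and optional copy number and
#' recurrence flag.  `size_class` is derived from the interval length.
#' Mixing genome builds within one panel is rejected (no liftover is ever
#' attempted).  When `copy_number` is given it must be consistent with
#' `dosage_type` for autosomes: loss implies CN < 2, gain implies CN > 2.
#'
#' @param id opaque call identifiers (unique)
#' @param chrom,start,end,build interval fields, see [gintv()]
#' @param dosage_type `"loss"` or `"gain"` per call
#' @param copy_number optional non-negative integer copy number (NA ok)
#' @param recurrent optional logical: recurrent-locus CNV (NA ok)
#' @param band optional cytogenetic band label carried as free text
#' @return data.frame of class `"cnv_panel"`
#' @examples
#' p <- cnv_panel("del1", "17", 1551800, 2264023, dosage_type = "loss",
#'                copy_number = 1)
#' p$size_class   # "<1 Mb"
#' @export
cnv_panel <- function(id, chrom, start, end, dosage_type,
                      build = "GRCh37", copy_number = NA,
                      recurrent = NA, band = NA_character_) {
  n <- max(length(id), length(chrom), length(start), length(end),
           length(build), length(dosage_type))
  gi <- gintv(rep_len(chrom, n), rep_len(start, n), rep_len(end, n),
              rep_len(build, n))
  id <- as.character(rep_len(id, n))
  if (anyDuplicated(id)) {
    abort(sprintf("duplicate CNV id(s): %s",
                  paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  dosage_type <- as.character(rep_len(dosage_type, n))
  if (!all(dosage_type %in% c("loss", "gain"))) {
    abort("dosage_type must be 'loss' or 'gain'")
  }
  if (length(unique(gi$build)) > 1) {
    abort(sprintf("panel mixes genome builds: %s (no liftover supported)",
                  paste(unique(gi$build), collapse = ", ")))
  }
  copy_number <- suppressWarnings(as.integer(rep_len(copy_number, n)))
  if (any(!is.na(copy_number) & copy_number < 0)) {
    abort("copy_number must be non-negative")
  }
  auto <- gi$chrom %in% as.character(1:22)
  bad_cn <- !is.na(copy_number) & auto &
    ((dosage_type == "loss" & copy_number >= 2) |
     (dosage_type == "gain" & copy_number <= 2))
  if (any(bad_cn)) {
    abort(sprintf(
      "copy_number inconsistent with dosage_type for: %s (autosomal loss needs CN < 2, gain CN > 2)",
      paste(id[bad_cn], collapse = ", ")))
  }
  structure(
    data.frame(id = id, chrom = gi$chrom, start = gi$start, end = gi$end,
               build = gi$build, dosage_type = dosage_type,
               copy_number = copy_number,
               recurrent = as.logical(rep_len(recurrent, n)),
               band = as.character(rep_len(band, n)),
               size_class = size_class(interval_length(gi)),
               stringsAsFactors = FALSE),
    class = c("cnv_panel", "data.frame"))
}

#' @export
print.cnv_panel <- function(x, ...) {
  cat(sprintf("CNV panel: %d call(s) [%d loss, %d gain], build %s\n",
              nrow(x), sum(x$dosage_type == "loss"),
              sum(x$dosage_type == "gain"),
              paste(unique(x$build), collapse = "/")))
  cat("size bins:",
      paste(sprintf("%s=%d", size_bins(),
                    tabulate(factor(x$size_class, size_bins()), 4)),
            collapse = " "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
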