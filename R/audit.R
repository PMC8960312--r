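# closed enumeration of discordance reasons, one per documented
# reason/problem row, keyed to the rubric section it implicates
REASON_SECTIONS <- c(
  S1_CONTENT_MISAPPLIED = 1L,
  S2_REGION_EVAL_ERROR = 2L,
  S2_AR_GENE_DIRECT_2A = 2L,
  S2_UNCURATED_SYNDROME = 2L,
  S2_POINT_DISAGREEMENT = 2L,
  S2_PHENOTYPE_2J_2K = 2L,
  S3_GENE_FAMILY = 3L,
  S4_GENE_OF_INTEREST = 4L,
  S4_CASE_DATA_SCRUTINY = 4L,
  S4_CASE_DATA_USE = 4L,
  S4_WEIGHT_UP_DOWN = 4L,
  S4_CASE_CONTROL_POP = 4L,
  S4_PHENOTYPE_SPECIFICITY = 4L,
  S4_SEGREGATION = 4L,
  S4_DE_NOVO = 4L,
  S4_IMPRINT_PENETRANCE = 4L)

#' Discordance reason vocabulary
#'
#' The closed set of reason codes used to tag why laboratories disagreed
#' on a CNV, with the rubric section each implicates.  Reasons are
#' assigned by human reviewers (or by the simulator's error modes) and
#' tallied verbatim; they are never inferred from score differences.
#'
#' @return data.frame with columns `code` and `section`
#' @export
discordance_reasons <- function() {
  data.frame(code = names(REASON_SECTIONS),
             section = unname(REASON_SECTIONS),
             stringsAsFactors = FALSE)
}

# "P,VUS" -> c("P","VUS"); canonical set order most-pathogenic first
parse_labels <- function(s) {
  labs <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  labs <- labs[nzchar(labs)]
  bad <- setdiff(labs, CLASS_LEVELS)
  if (length(bad)) {
    abort(sprintf("label(s) outside the five-tier vocabulary: %s",
                  paste(bad, collapse = ", ")))
  }
  labs
}

pattern_key <- function(s) {
  labs <- unique(parse_labels(s))
  paste(labs[order(match(labs, rev(CLASS_LEVELS)))], collapse = ",")
}

#' Construct review records
#'
#' One record per re-evaluated CNV: its initial multi-laboratory label
#' pattern, the pattern after consensus review, and any reason tags.
#' An initially *concordant* record is only admitted when flagged
#' `forced_review` (a panel may re-review a fully concordant call that
#' central scoring suggests is misclassified).
#'
#' @param cnv_id identifiers
#' @param dosage_type `"loss"`/`"gain"` per record
#' @param initial_labels,final_labels comma-joined label sets
#'   (e.g. `"P,VUS"`); order and multiplicity are irrelevant
#' @param reasons comma-joined [discordance_reasons()] codes (may be "")
#' @param forced_review logical
#' @return data.frame of class `"review_records"`
#' @export
review_records <- function(cnv_id, dosage_type, initial_labels,
                           final_labels, reasons = "",
                           forced_review = FALSE) {
  n <- length(cnv_id)
  df <- data.frame(cnv_id = as.character(cnv_id),
                   dosage_type = as.character(rep_len(dosage_type, n)),
                   initial_labels = as.character(rep_len(initial_labels, n)),
                   final_labels = as.character(rep_len(final_labels, n)),
                   reasons = as.character(rep_len(reasons, n)),
                   forced_review = as.logical(rep_len(forced_review, n)),
                   stringsAsFactors = FALSE)
  if (!all(df$dosage_type %in% c("loss", "gain"))) {
    abort("dosage_type must be 'loss' or 'gain'")
  }
  for (i in seq_len(n)) {
    init <- parse_labels(df$initial_labels[i])
    parse_labels(df$final_labels[i])  # validate
    if (conflict_class(init) == "complete" && !df$forced_review[i]) {
      abort(sprintf(
        "record %s has a concordant initial pattern (%s) but is not flagged forced_review",
        df$cnv_id[i], df$initial_labels[i]))
    }
    codes <- trimws(strsplit(df$reasons[i], ",", fixed = TRUE)[[1]])
    codes <- codes[nzchar(codes)]
    bad <- setdiff(codes, names(REASON_SECTIONS))
    if (length(bad)) {
      abort(sprintf("unknown reason code(s): %s",
                    paste(bad, collapse = ", ")))
    }
  }
  class(df) <- c("review_records", "data.frame")
  df
}

#' Expand (pattern, count) rows into individual review records
#'
#' @param patterns data.frame with columns `dosage_type`,
#'   `initial_labels`, `final_labels`, `count`, optional `forced_review`
#' @param prefix id prefix for the generated records
#' @return a [review_records()] data.frame with `sum(count)` rows
#' @export
expand_review_patterns <- function(patterns, prefix = "cnv") {
  rows <- patterns[rep(seq_len(nrow(patterns)), patterns$count), ,
                   drop = FALSE]
  review_records(
    cnv_id = sprintf("%s%03d", prefix, seq_len(nrow(rows))),
    dosage_type = rows$dosage_type,
    initial_labels = rows$initial_labels,
    final_labels = rows$final_labels,
    forced_review = as.logical(rows$forced_review %||% FALSE))
}

#' Bundled nine-laboratory re-review pattern table
#'
#' Initial and final classification patterns, with CNV counts, from a
#' published nine-laboratory CNV classification comparison in which all
#' initially discordant calls (39 deletions, 43 duplications) were
#' re-evaluated after the reasons for discordance were shared; one
#' additional deletion with complete initial VUS concordance was
#' re-reviewed by central request (`forced_review = 1`) and ended P vs
#' VUS.  Useful as a worked example and as a reference fixture for the
#' audit module.
#'
#' @return data.frame with columns `dosage_type`, `initial_labels`,
#'   `final_labels`, `count`, `forced_review`
#' @export
example_review_patterns <- function() {
  path <- system.file("extdata", "review_patterns.tsv",
                      package = "cnvconcord", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(rep("character", 3),
                                         "integer", "integer"))
  df$forced_review <- df$forced_review == 1
  df
}

#' Tabulate a re-evaluation round
#'
#' Groups records by dosage type and initial discordance pattern and
#' reports, per group: the CNV count, how many reached final complete
#' five-category concordance (and on which class), and the final
#' discordant patterns with counts.  Grand totals per dosage type
#' satisfy `n = resolved + still_discordant`.
#'
#' @param records a [review_records()] data.frame (non-empty)
#' @param include_forced include records flagged `forced_review`
#'   (default `TRUE`)
#' @return object of class `"review_tabulation"`: list with `groups`
#'   (data.frame), `totals` (data.frame per dosage type), `records`
#' @export
tabulate_review <- function(records, include_forced = TRUE) {
  stopifnot(inherits(records, "review_records"))
  if (!include_forced) records <- records[!records$forced_review, ]
  if (nrow(records) == 0) abort("no review records to tabulate")
  init_key <- vapply(records$initial_labels, pattern_key, "")
  final_key <- vapply(records$final_labels, pattern_key, "")
  final_cc <- vapply(final_key, function(k) conflict_class(parse_labels(k)),
                     "")
  resolved <- final_cc == "complete"
  grp <- paste(records$dosage_type, init_key, sep = "\r")
  groups <- do.call(rbind, lapply(unique(grp), function(g) {
    i <- which(grp == g)
    res_tab <- table(final_key[i][resolved[i]])
    dis_tab <- table(final_key[i][!resolved[i]])
    fmt <- function(tb) paste(sprintf("%s %d", names(tb), as.integer(tb)),
                              collapse = "; ")
    data.frame(dosage_type = records$dosage_type[i[1]],
               initial_pattern = init_key[i[1]],
               n = length(i),
               n_resolved = sum(resolved[i]),
               n_discordant = sum(!resolved[i]),
               resolved_classes = fmt(res_tab),
               final_patterns = fmt(dis_tab),
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  totals <- do.call(rbind, lapply(unique(records$dosage_type), function(d) {
    i <- records$dosage_type == d
    data.frame(dosage_type = d, n = sum(i),
               n_resolved = sum(resolved[i]),
               n_discordant = sum(!resolved[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(totals) <- NULL
  records$final_conflict_class <- final_cc
  structure(list(groups = groups, totals = totals, records = records),
            class = "review_tabulation")
}

#' @export
print.review_tabulation <- function(x, ...) {
  cat("Re-evaluation tabulation\n")
  print.data.frame(x$groups, row.names = FALSE)
  cat("totals:\n")
  print.data.frame(x$totals, row.names = FALSE)
  n <- nrow(x$records)
  mgmt <- sum(x$records$final_conflict_class == "management_impact")
  cat(sprintf("final complete concordance: %s; final management-impacting: %s\n",
              format_rate(sum(x$records$final_conflict_class == "complete"), n),
              format_rate(mgmt, n)))
  invisible(x)
}

#' Summarize discordance reasons by implicated section sets
#'
#' Buckets records by the *exact set* of rubric sections their reason
#' tags implicate ("Section 4 alone", "Section 2 + Section 4", ...).
#' Buckets partition the records: each record lands in exactly one.
#'
#' @param records a [review_records()] data.frame; every record must
#'   carry at least one reason tag
#' @return data.frame with columns `bucket`, `n`, `fraction`, sorted by
#'   descending `n`; zero rows for an empty record list
#' @export
reason_summary <- function(records) {
  stopifnot(inherits(records, "review_records"))
  if (nrow(records) == 0) {
    return(data.frame(bucket = character(), n = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  }
  buckets <- vapply(records$reasons, function(s) {
    codes <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
    codes <- codes[nzchar(codes)]
    if (length(codes) == 0) abort("record with empty reasons")
    secs <- sort(unique(REASON_SECTIONS[codes]))
    if (length(secs) == 1) sprintf("Section %d alone", secs)
    else paste(sprintf("Section %d", secs), collapse = " + ")
  }, "")
  tb <- sort(table(buckets), decreasing = TRUE)
  data.frame(bucket = names(tb), n = as.integer(tb),
             fraction = as.integer(tb) / nrow(records),
             stringsAsFactors = FALSE, row.names = NULL)
}
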