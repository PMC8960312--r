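CONFLICT_CLASSES <- c("complete", "confidence_difference", "ror_impact",
                      "management_impact")

#' Conflict-severity class of a multi-laboratory label pattern
#'
#' Classifies the (multi)set of five-tier classifications assigned to one
#' CNV across laboratories:
#'
#' * `complete` — all laboratories assigned the identical class;
#' * `management_impact` — P or LP co-occurs with any of VUS, LB, B: the
#'   disagreement could change medical management;
#' * `ror_impact` — no P/LP involvement, but VUS co-occurs with LB or B:
#'   the disagreement could change whether the result is returned;
#' * `confidence_difference` — disagreement confined to P vs LP, or to
#'   LB vs B: same clinical recommendation either way.
#'
#' Severity precedence for patterns spanning three groups (e.g.
#' {P, VUS, LB}) is management > ROR > confidence.
#'
#' @param labels character vector of classifications for one CNV (one per
#'   laboratory, order and multiplicity irrelevant); values restricted to
#'   P, LP, VUS, LB, B; must be non-empty
#' @return one of `"complete"`, `"confidence_difference"`,
#'   `"ror_impact"`, `"management_impact"`
#' @examples
#' conflict_class(c("P", "LP"))          # confidence_difference
#' conflict_class(c("P", "VUS", "LB"))   # management_impact
#' conflict_class(c("VUS", "LB"))        # ror_impact
#' @export
conflict_class <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) abort("empty classification label set")
  bad <- setdiff(unique(labels), CLASS_LEVELS)
  if (length(bad)) {
    abort(sprintf("label(s) outside the five-tier vocabulary: %s",
                  paste(bad, collapse = ", ")))
  }
  u <- unique(labels)
  if (length(u) == 1) return("complete")
  has_plp <- any(u %in% c("P", "LP"))
  has_low <- any(u %in% c("VUS", "LB", "B"))
  if (has_plp && has_low) return("management_impact")
  if ("VUS" %in% u && any(u %in% c("LB", "B"))) return("ror_impact")
  "confidence_difference"
}

#' The four conflict-severity class labels, least to most severe
#' @return character(4)
#' @export
conflict_classes <- function() CONFLICT_CLASSES

#' Construct a CNV-by-laboratory classification matrix
#'
#' @param cells character matrix of five-tier labels; rownames are CNV
#'   ids, colnames are laboratory ids.  `NA` cells mean the laboratory
#'   made no call for that CNV and are dropped row-wise before analysis
#'   (defensive: complete panels have no `NA`s).
#' @param meta optional per-CNV metadata data.frame with column `cnv_id`
#'   and any of `dosage_type`, `recurrent`, `panel`, `phase`
#' @return object of class `"classification_matrix"`
#' @export
classification_matrix <- function(cells, meta = NULL) {
  cells <- as.matrix(cells)
  if (is.null(rownames(cells)) || is.null(colnames(cells))) {
    abort("cells must carry CNV ids as rownames and lab ids as colnames")
  }
  vals <- unique(as.vector(cells))
  bad <- setdiff(vals[!is.na(vals)], CLASS_LEVELS)
  if (length(bad)) {
    idx <- which(matrix(cells %in% bad, nrow(cells)), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "label '%s' at (cnv %s, lab %s) outside the five-tier vocabulary",
      cells[idx[1], idx[2]], rownames(cells)[idx[1]],
      colnames(cells)[idx[2]]))
  }
  all_na <- rowSums(!is.na(cells)) == 0
  if (any(all_na)) {
    abort(sprintf("CNV(s) with no call from any laboratory: %s",
                  paste(rownames(cells)[all_na], collapse = ", ")))
  }
  if (!is.null(meta)) {
    stopifnot(is.data.frame(meta), "cnv_id" %in% names(meta))
    meta <- meta[match(rownames(cells), meta$cnv_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(list(cells = cells, meta = meta),
            class = "classification_matrix")
}

#' Concordance summary of a classification matrix
#'
#' Applies [conflict_class()] to every CNV row and tallies the four
#' conflict-severity classes.  Reports, per the field's convention:
#' the complete five-category concordance rate; the clinically meaningful
#' concordance rate (complete + confidence differences, which share one
#' clinical recommendation); per-class complete-concordance counts (how
#' many CNVs all laboratories called P, LP, ...); and, when metadata is
#' available, the same tallies within dosage-type / recurrence / panel
#' subsets.
#'
#' @param m a [classification_matrix()]
#' @param subsets compute metadata subset breakdowns (default `TRUE`;
#'   sub-summaries themselves carry no further breakdown)
#' @return object of class `"concordance_summary"`: list with `n_cnvs`,
#'   `counts` and `rates` (named by [conflict_classes()]),
#'   `complete_by_class`, `clinically_meaningful_rate`, `per_cnv`
#'   (data.frame cnv_id/conflict_class), `subsets` (list of sub-summaries)
#' @export
summarize_concordance <- function(m, subsets = TRUE) {
  stopifnot(inherits(m, "classification_matrix"))
  if (nrow(m$cells) == 0) abort("empty classification matrix")
  cc <- apply(m$cells, 1, function(row) conflict_class(row[!is.na(row)]))
  counts <- vapply(CONFLICT_CLASSES, function(k) sum(cc == k), integer(1))
  n <- nrow(m$cells)
  complete_by_class <- vapply(CLASS_LEVELS, function(cl) {
    sum(apply(m$cells, 1, function(row) {
      row <- row[!is.na(row)]
      length(unique(row)) == 1 && row[1] == cl
    }))
  }, integer(1))
  per_cnv <- data.frame(cnv_id = rownames(m$cells), conflict_class = cc,
                        stringsAsFactors = FALSE, row.names = NULL)
  subset_list <- list()
  if (subsets && !is.null(m$meta)) {
    for (col in intersect(c("dosage_type", "recurrent", "panel"),
                          names(m$meta))) {
      vals <- unique(m$meta[[col]])
      vals <- vals[!is.na(vals)]
      for (v in vals) {
        keep <- which(!is.na(m$meta[[col]]) & m$meta[[col]] == v)
        if (length(keep) == 0) next
        sub <- classification_matrix(m$cells[keep, , drop = FALSE],
                                     m$meta[keep, , drop = FALSE])
        subset_list[[paste0(col, "=", v)]] <-
          summarize_concordance(sub, subsets = FALSE)
      }
    }
  }
  structure(list(
    n_cnvs = n, counts = counts, rates = counts / n,
    complete_by_class = complete_by_class,
    clinically_meaningful_rate =
      (counts[["complete"]] + counts[["confidence_difference"]]) / n,
    per_cnv = per_cnv, subsets = subset_list),
    class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  n <- x$n_cnvs
  cat(sprintf("Inter-laboratory concordance over %d CNV(s)\n", n))
  cat(sprintf("  complete five-category concordance: %s\n",
              format_rate(x$counts[["complete"]], n)))
  cat(sprintf("  clinically meaningful concordance:  %s\n",
              format_rate(x$counts[["complete"]] +
                          x$counts[["confidence_difference"]], n)))
  cat(sprintf("  confidence differences:             %s\n",
              format_rate(x$counts[["confidence_difference"]], n)))
  cat(sprintf("  conflicts impacting management:     %s\n",
              format_rate(x$counts[["management_impact"]], n)))
  cat(sprintf("  conflicts impacting ROR:            %s\n",
              format_rate(x$counts[["ror_impact"]], n)))
  nz <- x$complete_by_class[x$complete_by_class > 0]
  if (length(nz)) {
    cat("  complete concordance by class:",
        paste(sprintf("%s=%d", names(nz), nz), collapse = " "), "\n")
  }
  for (nm in names(x$subsets)) {
    s <- x$subsets[[nm]]
    cat(sprintf("  [%s] complete %s, management %s\n", nm,
                format_rate(s$counts[["complete"]], s$n_cnvs),
                format_rate(s$counts[["management_impact"]], s$n_cnvs)))
  }
  invisible(x)
}

#' Tally conflict classes over (pattern, count) pairs
#'
#' Published comparisons often report discordance as label *patterns* with
#' CNV counts ("P or VUS: 10 CNVs") rather than per-laboratory detail.
#' `partition_counts` classifies each pattern with [conflict_class()] and
#' sums the counts per conflict class.
#'
#' @param patterns data.frame with columns `labels` (comma-joined label
#'   set, e.g. `"P,VUS"`) and `count` (positive integer)
#' @return named integer vector over [conflict_classes()]
#' @examples
#' partition_counts(data.frame(labels = c("P,LP", "P,VUS"), count = c(3, 10)))
#' @export
partition_counts <- function(patterns) {
  out <- stats::setNames(integer(length(CONFLICT_CLASSES)), CONFLICT_CLASSES)
  if (is.null(patterns) || nrow(patterns) == 0) return(out)
  if (any(patterns$count <= 0)) abort("pattern counts must be positive")
  for (i in seq_len(nrow(patterns))) {
    labs <- strsplit(patterns$labels[i], ",", fixed = TRUE)[[1]]
    labs <- trimws(labs)
    cls <- conflict_class(labs)
    out[cls] <- out[cls] + as.integer(patterns$count[i])
  }
  out
}

#' Pearson chi-square comparison of two proportions
#'
#' Compares `k1/n1` with `k2/n2` by the Pearson chi-square test on the
#' 2x2 table `[[k1, n1-k1], [k2, n2-k2]]` without continuity correction,
#' 1 degree of freedom, flagging significance at the 0.05 threshold.
#'
#' @param k1,n1 successes and total in group 1
#' @param k2,n2 successes and total in group 2
#' @return list with `statistic`, `p_value`, `significant` (p < .05),
#'   and the input `table`
#' @examples
#' compare_rates(41, 234, 177, 234)$significant   # TRUE
#' @export
compare_rates <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2) {
    abort("need 0 <= k <= n and n >= 1 in both groups")
  }
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    abort("a 2x2 expected cell is 0: chi-square invalid, use an exact test")
  }
  stat <- sum((tab - expected)^2 / expected)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p, significant = p < 0.05, table = tab)
}
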