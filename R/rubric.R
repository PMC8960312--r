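CLASS_LEVELS <- c("B", "LB", "VUS", "LP", "P")  # benign -> pathogenic

#' The five-tier classification vocabulary, most benign first
#' @return `c("B", "LB", "VUS", "LP", "P")`
#' @export
classification_levels <- function() CLASS_LEVELS

#' Load a scoring rubric
#'
#' A rubric is the data-driven form of the point-based scoring metric for
#' one dosage type: evidence categories grouped into five sections
#' (1 genomic content, 2 dosage sensitivity, 3 gene number, 4 published /
#' database / case-control evidence, 5 inheritance and family history),
#' each with default/min/max points, plus the five-tier classification
#' thresholds.  With `config = NULL` the rubric shipped with the package
#' is returned; these built-in tables encode the 2020 technical-standard
#' point values and are fully editable — pass your own JSON file to
#' change any category, range or threshold.
#'
#' @param dosage_type `"loss"` or `"gain"`
#' @param config optional path to a rubric JSON file; its `dosage_type`
#'   must match
#' @return object of class `"cnv_rubric"`: list with `dosage_type`,
#'   `categories` (data.frame), `thresholds`, `exclusive` (list of
#'   mutually exclusive code groups), `source` (file path)
#' @examples
#' rb <- load_rubric("gain")
#' rubric_category(rb, "2K")$default_points   # 0.45
#' @export
load_rubric <- function(dosage_type = c("loss", "gain"), config = NULL) {
  dosage_type <- match.arg(dosage_type)
  path <- config %||% system.file(
    "extdata", paste0("rubric_", dosage_type, ".json"),
    package = "cnvconcord", mustWork = TRUE)
  if (!file.exists(path)) abort(sprintf("rubric config not found: %s", path))
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!identical(cfg$dosage_type, dosage_type)) {
    abort(sprintf("rubric config is for dosage_type '%s', requested '%s'",
                  cfg$dosage_type, dosage_type))
  }
  cats <- cfg$categories
  need <- c("code", "section", "default", "min", "max")
  miss <- setdiff(need, names(cats))
  if (length(miss)) {
    abort(sprintf("rubric config lacks category field(s): %s",
                  paste(miss, collapse = ", ")))
  }
  categories <- data.frame(
    code = as.character(cats$code),
    section = as.integer(cats$section),
    default_points = as.numeric(cats$default),
    min_points = as.numeric(cats$min),
    max_points = as.numeric(cats$max),
    count_min = if ("count_min" %in% names(cats))
      suppressWarnings(as.numeric(cats$count_min)) else NA_real_,
    count_max = if ("count_max" %in% names(cats))
      suppressWarnings(as.numeric(cats$count_max)) else NA_real_,
    description = if ("description" %in% names(cats))
      as.character(cats$description) else "",
    stringsAsFactors = FALSE)
  dup <- categories$code[duplicated(categories$code)]
  if (length(dup)) {
    abort(sprintf("duplicate category code(s) in rubric: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  bad <- with(categories,
              !(min_points <= default_points & default_points <= max_points))
  if (any(bad)) {
    abort(sprintf("inverted point range for category %s",
                  paste(categories$code[bad], collapse = ", ")))
  }
  missing_sections <- setdiff(1:5, unique(categories$section))
  if (length(missing_sections)) {
    abort(sprintf("rubric missing section(s): %s",
                  paste(missing_sections, collapse = ", ")))
  }
  if (sum(categories$section == 1) != 2) {
    abort("rubric must contain exactly one Section-1 pair (content / no content)")
  }
  th <- cfg$thresholds
  for (f in c("p_min", "lp_min", "lb_max", "b_max")) {
    if (is.null(th[[f]])) abort(sprintf("thresholds block lacks '%s'", f))
  }
  th <- lapply(th[c("p_min", "lp_min", "lb_max", "b_max")], as.numeric)
  if (!(th$b_max < th$lb_max && th$lb_max < th$lp_min &&
        th$lp_min < th$p_min)) {
    abort("thresholds must satisfy b_max < lb_max < lp_min < p_min")
  }
  exclusive <- cfg$exclusive %||% list()
  if (is.matrix(exclusive)) {  # jsonlite simplifies a ragged-free array
    exclusive <- lapply(seq_len(nrow(exclusive)),
                        function(i) exclusive[i, ])
  }
  unknown <- setdiff(unlist(exclusive), categories$code)
  if (length(unknown)) {
    abort(sprintf("exclusive group names unknown category: %s",
                  paste(unknown, collapse = ", ")))
  }
  structure(list(dosage_type = dosage_type, categories = categories,
                 thresholds = th, exclusive = exclusive, source = path),
            class = "cnv_rubric")
}

#' Write a rubric back to its JSON config form
#'
#' Inverse of [load_rubric()]: a rubric written with `write_rubric()` and
#' reloaded compares equal category-by-category.
#'
#' @param rubric a `cnv_rubric`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_rubric <- function(rubric, path) {
  stopifnot(inherits(rubric, "cnv_rubric"))
  cats <- rubric$categories
  cat_list <- lapply(seq_len(nrow(cats)), function(i) {
    x <- list(code = cats$code[i], section = cats$section[i],
              default = cats$default_points[i], min = cats$min_points[i],
              max = cats$max_points[i],
              description = cats$description[i])
    if (!is.na(cats$count_min[i])) x$count_min <- cats$count_min[i]
    if (!is.na(cats$count_max[i])) x$count_max <- cats$count_max[i]
    x
  })
  jsonlite::write_json(
    list(dosage_type = rubric$dosage_type, thresholds = rubric$thresholds,
         exclusive = rubric$exclusive, categories = cat_list),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Look up one rubric category
#'
#' @param rubric a `cnv_rubric`
#' @param code category code, e.g. `"2K"`
#' @return one-row data.frame, or error if the code is absent
#' @export
rubric_category <- function(rubric, code) {
  stopifnot(inherits(rubric, "cnv_rubric"))
  i <- match(code, rubric$categories$code)
  if (is.na(i)) {
    abort(sprintf("unknown category code '%s' in %s rubric",
                  code, rubric$dosage_type))
  }
  rubric$categories[i, , drop = FALSE]
}

#' @export
print.cnv_rubric <- function(x, ...) {
  cat(sprintf("CNV scoring rubric (%s): %d categories, sections %s\n",
              x$dosage_type, nrow(x$categories),
              paste(sort(unique(x$categories$section)), collapse = ",")))
  cat(sprintf("thresholds: P >= %.2f, LP >= %.2f, LB <= %.2f, B <= %.2f\n",
              x$thresholds$p_min, x$thresholds$lp_min,
              x$thresholds$lb_max, x$thresholds$b_max))
  cat("config:", x$source, "\n")
  invisible(x)
}

#' Build evidence assignment rows
#'
#' One row per evidence category applied to a CNV by an evaluator.
#'
#' @param category_code rubric category codes
#' @param points points applied (recycled)
#' @param justification free-text justification (recycled)
#' @param provenance `"manual"` (worksheet) or `"auto"` (annotation-driven)
#' @return data.frame with columns `category_code`, `points`,
#'   `justification`, `provenance`
#' @export
ev_assign <- function(category_code, points, justification = "",
                      provenance = "manual") {
  n <- length(category_code)
  if (!all(provenance %in% c("auto", "manual"))) {
    abort("provenance must be 'auto' or 'manual'")
  }
  data.frame(category_code = as.character(category_code),
             points = as.numeric(rep_len(points, n)),
             justification = as.character(rep_len(justification, n)),
             provenance = as.character(rep_len(provenance, n)),
             stringsAsFactors = FALSE)
}

#' Validate an evidence assignment against a rubric
#'
#' Accepts an assignment iff its category exists in the rubric and its
#' points lie within the category's allowed `[min, max]` range (absolute
#' tolerance 1e-9).  Rejection is an error naming the category and the
#' allowed range — the decision points where laboratories were observed
#' to assign different points (e.g. 2C-1) are exactly what the range
#' check patrols.
#'
#' @param rubric a `cnv_rubric`
#' @param assignment data.frame from [ev_assign()] (one or more rows)
#' @return the assignment, invisibly, if every row is acceptable
#' @export
validate_assignment <- function(rubric, assignment) {
  stopifnot(inherits(rubric, "cnv_rubric"))
  for (i in seq_len(nrow(assignment))) {
    code <- assignment$category_code[i]
    cat_row <- rubric_category(rubric, code)  # errors on unknown code
    p <- assignment$points[i]
    if (p < cat_row$min_points - 1e-9 || p > cat_row$max_points + 1e-9) {
      abort(sprintf(
        "points %.4g out of range for category %s (allowed [%.4g, %.4g])",
        p, code, cat_row$min_points, cat_row$max_points))
    }
  }
  invisible(assignment)
}

#' Sum evidence points
#'
#' Plain arithmetic sum of validated assignment points.  At most one
#' assignment per category code; duplicates are an error naming the code.
#' The empty worksheet sums to 0 (and therefore classifies as VUS).
#'
#' @param assignments data.frame of assignments (possibly 0 rows)
#' @param rubric optional `cnv_rubric`; when given, mutually exclusive
#'   category groups (e.g. 2J vs 2K, two readings of the same breakpoint
#'   observation) are also rejected
#' @return numeric total (unrounded; display to 2 decimals)
#' @export
total_score <- function(assignments, rubric = NULL) {
  if (is.null(assignments) || nrow(assignments) == 0) return(0)
  dup <- assignments$category_code[duplicated(assignments$category_code)]
  if (length(dup)) {
    abort(sprintf("duplicate assignment for category %s",
                  paste(unique(dup), collapse = ", ")))
  }
  if (!is.null(rubric)) {
    for (grp in rubric$exclusive) {
      present <- intersect(grp, assignments$category_code)
      if (length(present) > 1) {
        abort(sprintf("mutually exclusive categories applied together: %s",
                      paste(present, collapse = " + ")))
      }
    }
  }
  sum(assignments$points)
}

#' Map a point total to the five-tier classification
#'
#' Monotone step function: `total >= p_min` is P; `[lp_min, p_min)` LP;
#' the open interval `(lb_max, lp_min)` VUS; `(b_max, lb_max]` LB; and
#' `<= b_max` B.  Computed on the unrounded total.
#'
#' @param total numeric vector of point totals
#' @param thresholds a thresholds list (`p_min`, `lp_min`, `lb_max`,
#'   `b_max`) or a `cnv_rubric` whose thresholds are used
#' @return character vector in `c("P","LP","VUS","LB","B")`
#' @examples
#' rb <- load_rubric("loss")
#' classify(c(-1, 0, 0.45, 0.9, 1), rb)  # "B" "VUS" "VUS" "LP" "P"
#' @export
classify <- function(total, thresholds) {
  if (inherits(thresholds, "cnv_rubric")) thresholds <- thresholds$thresholds
  th <- thresholds
  ifelse(total >= th$p_min, "P",
    ifelse(total >= th$lp_min, "LP",
      ifelse(total > th$lb_max, "VUS",
        ifelse(total > th$b_max, "LB", "B"))))
}

#' Score one CNV from its evidence worksheet
#'
#' Validates every assignment against the rubric (which must match the
#' CNV's dosage type), sums the points and classifies the total.
#'
#' @param cnv one row of a [cnv_panel()]
#' @param assignments data.frame of evidence assignments for this CNV
#' @param rubric a `cnv_rubric` with `dosage_type == cnv$dosage_type`
#' @return object of class `"score_result"`: list with `cnv_id`,
#'   `total_points`, `classification`, `assignments`
#' @export
score_cnv <- function(cnv, assignments, rubric) {
  stopifnot(inherits(rubric, "cnv_rubric"))
  if (nrow(cnv) != 1) abort("score_cnv expects exactly one CNV row")
  if (!identical(cnv$dosage_type, rubric$dosage_type)) {
    abort(sprintf("CNV %s is a %s but the rubric is for %s",
                  cnv$id, cnv$dosage_type, rubric$dosage_type))
  }
  if (is.null(assignments)) assignments <- ev_assign(character(0), numeric(0))
  validate_assignment(rubric, assignments)
  total <- total_score(assignments, rubric)
  structure(list(cnv_id = cnv$id, total_points = total,
                 classification = classify(total, rubric),
                 assignments = assignments),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("%s: %.2f points -> %s\n", x$cnv_id, x$total_points,
              x$classification))
  if (nrow(x$assignments)) {
    print.data.frame(x$assignments, row.names = FALSE)
  } else {
    cat("(no evidence applied)\n")
  }
  invisible(x)
}
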