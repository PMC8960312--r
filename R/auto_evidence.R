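# category applied when a CNV is completely contained in an established
# benign region, by dosage type (loss: contained-in-benign-CNV-region;
# gain: smaller-than-benign-gain without gene disruption)
BENIGN_CONTAINMENT_CODE <- c(loss = "2F", gain = "2D")

#' Section 1 — genomic content
#'
#' Returns `1A` iff the CNV overlaps at least one protein-coding gene or
#' other known functionally important element, otherwise `1B` ("completely
#' void of gene content").  Exactly one of the two is always returned;
#' misapplying them (1A for empty CNVs, 1B for gene-containing CNVs) is a
#' documented source of inter-laboratory discordance, so the rule is kept
#' deliberately mechanical.  Features with biotype `"other"` do not count
#' as content.
#'
#' @param cnv one [cnv_panel()] row
#' @param ann an [annotation_set()]
#' @param rubric the matching `cnv_rubric`
#' @return one-row assignment data.frame (provenance `"auto"`)
#' @export
assign_section1 <- function(cnv, ann, rubric) {
  hits <- genes_in(cnv, ann,
                   biotypes = c("protein_coding", "other_functional_element"))
  code <- if (nrow(hits) > 0) "1A" else "1B"
  just <- if (nrow(hits) > 0) {
    sprintf("overlaps %d protein-coding/functional element(s)", nrow(hits))
  } else {
    "no protein-coding gene or known functional element overlapped"
  }
  ev_assign(code, rubric_category(rubric, code)$default_points, just,
            provenance = "auto")
}

# is either CNV breakpoint at or within [start, end] of the feature?
# boundary positions count as inside: single-base breakpoint resolution of
# clinical calls is unreliable, so an exact-boundary call is treated as
# disrupting the gene
.breakpoint_inside <- function(cnv, feat) {
  (cnv$start >= feat$start & cnv$start <= feat$end) |
    (cnv$end >= feat$start & cnv$end <= feat$end)
}

#' Section 2 — dosage sensitivity
#'
#' Applies the deterministic part of the dosage-sensitivity section from
#' curated annotation.  Only records with `curated = TRUE` are treated as
#' "established"; uncurated reports (e.g. OMIM syndrome regions never
#' formally dosage-curated) produce a review flag and never points — their
#' direct use as category 2A is a documented error mode.
#'
#' Loss rubric: a completely contained established HI gene/region emits
#' `2A`; complete containment of the CNV within an established benign
#' region emits the benign-containment category (`2F`); partial dosage
#' region overlap emits no points, only a review flag naming the region.
#'
#' Gain rubric: a completely contained established TS gene/region emits
#' `2A`; a gain breakpoint falling inside an established HI gene emits
#' `2K` (0.45 points by default) whereas a gain that merely spans HI genes
#' without disrupting them emits `2J` (0 points) — never both; containment
#' within an established benign region emits `2D`.
#'
#' @param cnv one [cnv_panel()] row
#' @param ann an [annotation_set()]
#' @param rubric the matching `cnv_rubric`
#' @return list with `assignments` (data.frame, possibly 0 rows) and
#'   `flags` (character vector of human-review notes)
#' @export
assign_section2 <- function(cnv, ann, rubric) {
  stopifnot(inherits(rubric, "cnv_rubric"))
  if (!identical(cnv$dosage_type, rubric$dosage_type)) {
    abort(sprintf("CNV %s is a %s but the rubric is for %s",
                  cnv$id, cnv$dosage_type, rubric$dosage_type))
  }
  hits <- regions_in(cnv, ann)
  flags <- character(0)
  codes <- character(0)

  for (i in seq_len(nrow(hits))) {
    r <- hits[i, ]
    if (!r$curated) {
      flags <- c(flags, sprintf(
        "uncurated record '%s' (%s) overlaps %s: not auto-applied, review required",
        r$name, r$role, cnv$id))
      next
    }
    if (cnv$dosage_type == "loss") {
      if (r$role %in% c("HI_gene", "HI_region")) {
        if (r$cnv_contains_region) {
          codes <- c(codes, "2A")
        } else {
          flags <- c(flags, sprintf(
            "partial overlap of established %s '%s': no points auto-assigned, review required",
            r$role, r$name))
        }
      } else if (r$role == "benign_region") {
        if (r$region_contains_cnv) {
          codes <- c(codes, BENIGN_CONTAINMENT_CODE[["loss"]])
        } else {
          flags <- c(flags, sprintf(
            "partial overlap of established benign region '%s': review required",
            r$name))
        }
      }
      # TS records are not evidence for a loss; ignored silently
    } else {  # gain
      if (r$role %in% c("TS_gene", "TS_region")) {
        if (r$cnv_contains_region) {
          codes <- c(codes, "2A")
        } else {
          flags <- c(flags, sprintf(
            "partial overlap of established %s '%s': no points auto-assigned, review required",
            r$role, r$name))
        }
      } else if (r$role == "benign_region") {
        if (r$region_contains_cnv) {
          codes <- c(codes, BENIGN_CONTAINMENT_CODE[["gain"]])
        } else {
          flags <- c(flags, sprintf(
            "partial overlap of established benign region '%s': review required",
            r$name))
        }
      } else if (r$role == "HI_gene") {
        if (.breakpoint_inside(cnv, r)) {
          codes <- c(codes, "2K")
        } else if (r$cnv_contains_region) {
          codes <- c(codes, "2J")
        }
      }
    }
  }
  # one breakpoint observation, one reading: 2K (phenotype consistent with
  # HI-gene disruption) supersedes 2J, they are never co-emitted
  if ("2K" %in% codes) codes <- setdiff(codes, "2J")
  codes <- unique(codes)
  assignments <- if (length(codes)) {
    do.call(rbind, lapply(codes, function(code) {
      ev_assign(code, rubric_category(rubric, code)$default_points,
                sprintf("established dosage/benign annotation for %s", cnv$id),
                provenance = "auto")
    }))
  } else {
    ev_assign(character(0), numeric(0))
  }
  list(assignments = assignments, flags = flags)
}

#' Section 3 — gene number
#'
#' Counts protein-coding genes overlapping the CNV (via [genes_in()]) and
#' maps the count through the rubric's Section-3 gene-count bins.  With
#' `collapse_families = TRUE` a gene family counts once — reproducing the
#' "one gene or multiple genes" ambiguity that drives Section-3
#' discordance.  The realized count and the flag state are recorded in the
#' justification.
#'
#' @param cnv one [cnv_panel()] row
#' @param ann an [annotation_set()]
#' @param rubric the matching `cnv_rubric`
#' @param collapse_families logical (default `FALSE`)
#' @return one-row assignment data.frame
#' @export
assign_section3 <- function(cnv, ann, rubric, collapse_families = FALSE) {
  g <- genes_in(cnv, ann, collapse_families = collapse_families,
                biotypes = "protein_coding")
  n <- nrow(g)
  s3 <- rubric$categories[rubric$categories$section == 3, , drop = FALSE]
  lo <- ifelse(is.na(s3$count_min), 0, s3$count_min)
  hi <- ifelse(is.na(s3$count_max), Inf, s3$count_max)
  k <- which(n >= lo & n <= hi)
  if (length(k) != 1) {
    abort(sprintf(
      "gene count %d matches %d Section-3 bins (rubric bins must partition)",
      n, length(k)))
  }
  ev_assign(s3$code[k], s3$default_points[k],
            sprintf("%d protein-coding gene(s)%s", n,
                    if (collapse_families) " (families collapsed)" else ""),
            provenance = "auto")
}

#' Full annotation-driven worksheet (Sections 1-3)
#'
#' Convenience wrapper running [assign_section1()], [assign_section2()]
#' and [assign_section3()] for one CNV.  Sections 4 and 5 (case,
#' case-control, inheritance evidence) are never auto-assigned; they
#' arrive only through manual worksheets.
#'
#' @inheritParams assign_section3
#' @return list with `assignments` (data.frame) and `flags` (character)
#' @export
auto_worksheet <- function(cnv, ann, rubric, collapse_families = FALSE) {
  s1 <- assign_section1(cnv, ann, rubric)
  s2 <- assign_section2(cnv, ann, rubric)
  s3 <- assign_section3(cnv, ann, rubric, collapse_families)
  list(assignments = rbind(s1, s2$assignments, s3), flags = s2$flags)
}
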