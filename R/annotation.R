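GENE_BIOTYPES <- c("protein_coding", "other_functional_element", "other")
REGION_ROLES <- c("HI_gene", "HI_region", "TS_gene", "TS_region",
                  "benign_region")

#' Assemble an annotation set
#'
#' Bundles a gene track and a dosage-curation track for evidence
#' assignment.  `genes` holds gene features (symbol, interval, biotype,
#' optional family id); `regions` holds dosage-sensitivity and benign
#' region curation records.  Records with `curated = FALSE` (e.g. syndrome
#' regions reported in the literature but never formally dosage-curated)
#' are carried for review flagging but are never auto-applied as
#' established evidence.
#'
#' @param genes data.frame with columns `symbol`, `chrom`, `start`, `end`,
#'   `biotype` (one of `r paste(GENE_BIOTYPES, collapse=", ")`), optional
#'   `family_id`
#' @param regions data.frame with columns `name`, `chrom`, `start`, `end`,
#'   `role` (one of HI_gene, HI_region, TS_gene, TS_region,
#'   benign_region), `curated` (logical)
#' @return object of class `"annotation_set"`
#' @export
annotation_set <- function(genes = NULL, regions = NULL) {
  empty_genes <- data.frame(symbol = character(), chrom = character(),
                            start = numeric(), end = numeric(),
                            biotype = character(), family_id = character(),
                            stringsAsFactors = FALSE)
  empty_regions <- data.frame(name = character(), chrom = character(),
                              start = numeric(), end = numeric(),
                              role = character(), curated = logical(),
                              stringsAsFactors = FALSE)
  genes <- if (is.null(genes) || nrow(genes) == 0) empty_genes else {
    if (!all(nzchar(genes$symbol))) abort("gene symbol must be nonempty")
    gi <- gintv(genes$chrom, genes$start, genes$end)
    biotype <- as.character(genes$biotype %||% "protein_coding")
    if (!all(biotype %in% GENE_BIOTYPES)) {
      abort(sprintf("unknown biotype(s): %s",
                    paste(setdiff(unique(biotype), GENE_BIOTYPES),
                          collapse = ", ")))
    }
    data.frame(symbol = as.character(genes$symbol), chrom = gi$chrom,
               start = gi$start, end = gi$end, biotype = biotype,
               family_id = as.character(genes$family_id %||% NA),
               stringsAsFactors = FALSE)
  }
  regions <- if (is.null(regions) || nrow(regions) == 0) empty_regions else {
    gi <- gintv(regions$chrom, regions$start, regions$end)
    role <- as.character(regions$role)
    if (!all(role %in% REGION_ROLES)) {
      abort(sprintf("unknown region role(s): %s",
                    paste(setdiff(unique(role), REGION_ROLES),
                          collapse = ", ")))
    }
    data.frame(name = as.character(regions$name), chrom = gi$chrom,
               start = gi$start, end = gi$end, role = role,
               curated = as.logical(regions$curated),
               stringsAsFactors = FALSE)
  }
  # canonical order makes interval queries order-independent
  genes <- genes[order(genes$chrom, genes$start, genes$symbol), ,
                 drop = FALSE]
  regions <- regions[order(regions$chrom, regions$start, regions$name), ,
                     drop = FALSE]
  rownames(genes) <- rownames(regions) <- NULL
  structure(list(genes = genes, regions = regions),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d gene(s), %d region record(s)\n",
              nrow(x$genes), nrow(x$regions)))
  if (nrow(x$regions)) {
    tb <- table(x$regions$role, x$regions$curated)
    print(tb)
  }
  invisible(x)
}

#' Genes overlapped by a CNV
#'
#' Returns all gene features overlapping the CNV by at least 1 bp, in
#' stable (chrom, start, symbol) order.  With `collapse_families = TRUE`,
#' genes sharing a `family_id` are collapsed to a single representative
#' row (the first in sort order) — this reproduces the "large gene family
#' counted as one gene or as many" decision point that drives Section-3
#' discordance between laboratories.  Genes with no `family_id` are never
#' collapsed.
#'
#' @param cnv one row of a [cnv_panel()] (or any single interval row)
#' @param ann an [annotation_set()]
#' @param collapse_families logical; collapse family members to one row
#' @param biotypes restrict to these biotypes (default all)
#' @return data.frame of gene features (possibly 0 rows), with an
#'   `n_members` column giving the number of genes each row represents
#' @export
genes_in <- function(cnv, ann, collapse_families = FALSE,
                     biotypes = GENE_BIOTYPES) {
  stopifnot(inherits(ann, "annotation_set"))
  if (nrow(cnv) != 1) abort("genes_in expects exactly one CNV row")
  g <- ann$genes[ann$genes$biotype %in% biotypes, , drop = FALSE]
  if (nrow(g) == 0) {
    return(cbind(g, n_members = integer(0)))
  }
  hit <- overlap_bp(gintv(cnv$chrom, cnv$start, cnv$end),
                    gintv(g$chrom, g$start, g$end)) >= 1
  g <- g[hit, , drop = FALSE]
  g <- g[order(g$chrom, g$start, g$symbol), , drop = FALSE]
  if (collapse_families && nrow(g) > 0) {
    key <- ifelse(is.na(g$family_id) | !nzchar(g$family_id),
                  paste0(".solo.", g$symbol), g$family_id)
    first <- !duplicated(key)
    size <- as.integer(table(key)[key[first]])
    g <- g[first, , drop = FALSE]
    g$n_members <- size
  } else {
    g$n_members <- rep(1L, nrow(g))
  }
  rownames(g) <- NULL
  g
}

#' Regions overlapped by a CNV
#'
#' @param cnv one CNV row
#' @param ann an [annotation_set()]
#' @param roles restrict to these roles (default all)
#' @return region records overlapping by >= 1 bp, with logical columns
#'   `cnv_contains_region` and `region_contains_cnv`
#' @export
regions_in <- function(cnv, ann, roles = REGION_ROLES) {
  stopifnot(inherits(ann, "annotation_set"))
  if (nrow(cnv) != 1) abort("regions_in expects exactly one CNV row")
  r <- ann$regions[ann$regions$role %in% roles, , drop = FALSE]
  if (nrow(r) == 0) {
    r$cnv_contains_region <- logical(0)
    r$region_contains_cnv <- logical(0)
    return(r)
  }
  ci <- gintv(cnv$chrom, cnv$start, cnv$end)
  ri <- gintv(r$chrom, r$start, r$end)
  hit <- overlap_bp(ci, ri) >= 1
  r <- r[hit, , drop = FALSE]
  if (nrow(r)) {
    ri <- gintv(r$chrom, r$start, r$end)
    r$cnv_contains_region <- gi_contains(ci, ri)
    r$region_contains_cnv <- gi_contains(ri, ci)
  } else {
    r$cnv_contains_region <- logical(0)
    r$region_contains_cnv <- logical(0)
  }
  rownames(r) <- NULL
  r
}
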