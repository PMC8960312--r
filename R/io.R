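# ---- annotation loaders ----------------------------------------------------

#' Read a gene track from BED
#'
#' BED is 0-based half-open; import converts to the 1-based inclusive
#' coordinates used throughout.  Column 4 (name) becomes the gene symbol.
#' BED carries no biotype, so all features default to `protein_coding`
#' unless a sidecar is given; the optional sidecar TSV (columns `symbol`,
#' `family_id`, optional `biotype`) attaches family ids and biotypes.
#'
#' @param path BED file
#' @param sidecar optional TSV path with per-symbol `family_id`/`biotype`
#' @return gene data.frame suitable for [annotation_set()]
#' @export
read_genes_bed <- function(path, sidecar = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  gr <- rtracklayer::import(path, format = "BED")
  genes <- data.frame(
    symbol = if (!is.null(gr$name)) as.character(gr$name)
             else sprintf("bed_%d", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),  # already 1-based after import
    end = GenomicRanges::end(gr),
    biotype = "protein_coding", family_id = NA_character_,
    stringsAsFactors = FALSE)
  if (!is.null(sidecar)) {
    sc <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
    i <- match(genes$symbol, sc$symbol)
    if ("family_id" %in% names(sc)) genes$family_id <- sc$family_id[i]
    if ("biotype" %in% names(sc)) {
      genes$biotype <- ifelse(is.na(i), genes$biotype, sc$biotype[i])
    }
  }
  genes
}

#' Read a gene track from GFF3
#'
#' Keeps `gene` features; GFF3 is already 1-based inclusive and passes
#' through.  The symbol is taken from the `Name` (fallback `ID`)
#' attribute, the biotype from `gene_biotype`/`biotype` (values other
#' than `protein_coding` and `other_functional_element` collapse to
#' `other`), and an optional `family_id` attribute is honoured.
#'
#' @param path GFF3 file
#' @return gene data.frame suitable for [annotation_set()]
#' @export
read_genes_gff3 <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  meta <- as.data.frame(S4Vectors::mcols(gr))
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(meta)) return(as.character(meta[[nm]]))
    rep(NA_character_, length(gr))
  }
  symbol <- pick("Name", "gene_name", "ID")
  biotype <- pick("gene_biotype", "biotype")
  biotype[is.na(biotype)] <- "protein_coding"
  biotype[!biotype %in% GENE_BIOTYPES] <- "other"
  data.frame(symbol = symbol,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             biotype = biotype, family_id = pick("family_id"),
             stringsAsFactors = FALSE)
}

#' Read a dosage/benign region curation table
#'
#' TSV columns: `name`, `chrom`, `start`, `end`, `role` (HI_gene,
#' HI_region, TS_gene, TS_region, benign_region), `curated` (0/1).
#'
#' @param path TSV file
#' @return region data.frame suitable for [annotation_set()]
#' @export
read_regions_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "chrom", "start", "end", "role", "curated")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("region table lacks column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  df$curated <- df$curated %in% c(1, "1", TRUE, "TRUE", "true")
  df
}

# ---- CNV call readers ------------------------------------------------------

#' Read CNV calls from a TSV table
#'
#' Required columns: `id`, `chrom`, `start`, `end`, `dosage_type`
#' (loss/gain); optional `copy_number`, `recurrent` (0/1), `build`,
#' `band`.  Columns are matched by header name, order-free; `.` denotes a
#' missing optional value.  Malformed rows are reported with their line
#' number (header = line 1).
#'
#' @param path TSV file
#' @return a [cnv_panel()]
#' @export
read_cnv_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", "."))
  need <- c("id", "chrom", "start", "end", "dosage_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("CNV table lacks column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  bad <- which(!is.finite(start) | !is.finite(end) | start < 1 | end < start)
  if (length(bad)) {
    abort(sprintf("malformed CNV row(s) at line %s of %s (need 1 <= start <= end)",
                  paste(bad + 1, collapse = ", "), path))
  }
  cnv_panel(id = df$id, chrom = df$chrom, start = start, end = end,
            dosage_type = df$dosage_type,
            build = if ("build" %in% names(df))
              ifelse(is.na(df$build), "GRCh37", df$build) else "GRCh37",
            copy_number = df$copy_number %||% NA,
            recurrent = if ("recurrent" %in% names(df))
              df$recurrent %in% c(1, "1", TRUE, "TRUE") else NA,
            band = df$band %||% NA_character_)
}

#' Read CNV calls from a structural-variant VCF
#'
#' Accepts records with `INFO/SVTYPE` of `DEL` (mapped to loss) or `DUP`
#' (gain) and an `INFO/END` coordinate; VCF `POS`/`END` are 1-based and
#' map directly to the inclusive interval.  Records of other SV types
#' are skipped with a warning reporting the count.  Read-only: the
#' package never writes VCF.
#'
#' @param path VCF file (uncompressed or bgzipped)
#' @param build genome-build tag to stamp on the panel (default GRCh37)
#' @return a [cnv_panel()]
#' @export
read_cnv_vcf <- function(path, build = "GRCh37") {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  vcf <- VariantAnnotation::readVcf(path, genome = build)
  info <- VariantAnnotation::info(vcf)
  svtype <- as.character(info$SVTYPE)
  if (is.null(svtype) || all(is.na(svtype))) {
    abort(sprintf("no SVTYPE INFO field in %s", path))
  }
  keep <- svtype %in% c("DEL", "DUP")
  if (any(!keep)) {
    warning(sprintf("%d record(s) with unsupported SVTYPE skipped",
                    sum(!keep)))
  }
  if (!any(keep)) abort(sprintf("no DEL/DUP records in %s", path))
  rr <- SummarizedExperiment::rowRanges(vcf)[keep]
  end <- unlist(info$END[keep])
  ids <- names(rr)
  if (is.null(ids)) ids <- sprintf("sv_%d", seq_along(rr))
  cnv_panel(id = ids,
            chrom = as.character(GenomicRanges::seqnames(rr)),
            start = GenomicRanges::start(rr), end = end,
            dosage_type = ifelse(svtype[keep] == "DEL", "loss", "gain"),
            build = build)
}

# ---- matrices, worksheets, summaries ---------------------------------------

#' Read a classification matrix from TSV
#'
#' First column `cnv_id`, one column per laboratory, values restricted to
#' P/LP/VUS/LB/B (`.` = no call).  An optional metadata sidecar TSV
#' (column `cnv_id` plus any of `dosage_type`, `recurrent`, `panel`,
#' `phase`) attaches per-CNV metadata.
#'
#' @param path matrix TSV
#' @param meta optional sidecar TSV path
#' @return a [classification_matrix()]
#' @export
read_matrix <- function(path, meta = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", "."))
  if (names(df)[1] != "cnv_id") {
    abort("first column of a classification matrix must be 'cnv_id'")
  }
  cells <- as.matrix(df[, -1, drop = FALSE])
  rownames(cells) <- df$cnv_id
  md <- NULL
  if (!is.null(meta)) {
    md <- utils::read.delim(meta, stringsAsFactors = FALSE)
    if ("recurrent" %in% names(md)) {
      md$recurrent <- md$recurrent %in% c(1, "1", TRUE, "TRUE")
    }
  }
  classification_matrix(cells, md)
}

#' Write a classification matrix to TSV
#' @param m a [classification_matrix()]
#' @param path output TSV; metadata, if any, goes to `<path>.meta.tsv`
#' @return `path`, invisibly
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "classification_matrix"))
  df <- data.frame(cnv_id = rownames(m$cells), m$cells,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  if (!is.null(m$meta)) {
    utils::write.table(m$meta, paste0(path, ".meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = ".")
  }
  invisible(path)
}

#' Read an evidence worksheet
#'
#' TSV columns (order-free): `cnv_id`, `lab_id`, `category_code`,
#' `points`, `justification`, optional `provenance` (defaults manual).
#'
#' @param path worksheet TSV
#' @return worksheet data.frame
#' @export
read_worksheet <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", "."))
  need <- c("cnv_id", "lab_id", "category_code", "points")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("worksheet lacks column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  df$points <- as.numeric(df$points)
  df$justification <- as.character(df$justification %||% "")
  df$justification[is.na(df$justification)] <- ""
  df$provenance <- as.character(df$provenance %||% "manual")
  df$provenance[is.na(df$provenance)] <- "manual"
  df[, c("cnv_id", "lab_id", "category_code", "points", "justification",
         "provenance")]
}

#' Write an evidence worksheet
#' @param ws worksheet data.frame (see [read_worksheet()])
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_worksheet <- function(ws, path) {
  cols <- c("cnv_id", "lab_id", "category_code", "points", "justification",
            "provenance")
  utils::write.table(ws[, intersect(cols, names(ws)), drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  invisible(path)
}

# flatten one summary to a single row
.summary_row <- function(scope, s) {
  data.frame(scope = scope, n_cnvs = s$n_cnvs,
             complete = s$counts[["complete"]],
             confidence_difference = s$counts[["confidence_difference"]],
             ror_impact = s$counts[["ror_impact"]],
             management_impact = s$counts[["management_impact"]],
             complete_P = s$complete_by_class[["P"]],
             complete_LP = s$complete_by_class[["LP"]],
             complete_VUS = s$complete_by_class[["VUS"]],
             complete_LB = s$complete_by_class[["LB"]],
             complete_B = s$complete_by_class[["B"]],
             stringsAsFactors = FALSE)
}

#' Write a concordance summary to TSV
#'
#' One row per scope: `overall` first, then any metadata subsets.  Counts
#' round-trip exactly through [read_summary()].
#'
#' @param summary a `concordance_summary`
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "concordance_summary"))
  rows <- rbind(.summary_row("overall", summary),
                do.call(rbind, lapply(names(summary$subsets), function(nm) {
                  .summary_row(nm, summary$subsets[[nm]])
                })))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a concordance summary written by [write_summary()]
#'
#' @param path summary TSV
#' @return a `concordance_summary` (without per-CNV detail)
#' @export
read_summary <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  build <- function(row) {
    counts <- c(complete = row$complete,
                confidence_difference = row$confidence_difference,
                ror_impact = row$ror_impact,
                management_impact = row$management_impact)
    counts <- stats::setNames(as.integer(counts), names(counts))
    cbc <- stats::setNames(
      as.integer(c(row$complete_B, row$complete_LB, row$complete_VUS,
                   row$complete_LP, row$complete_P)), CLASS_LEVELS)
    structure(list(
      n_cnvs = row$n_cnvs, counts = counts, rates = counts / row$n_cnvs,
      complete_by_class = cbc,
      clinically_meaningful_rate =
        (counts[["complete"]] + counts[["confidence_difference"]]) /
        row$n_cnvs,
      per_cnv = NULL, subsets = list()), class = "concordance_summary")
  }
  overall <- build(df[df$scope == "overall", ][1, ])
  for (i in which(df$scope != "overall")) {
    overall$subsets[[df$scope[i]]] <- build(df[i, ])
  }
  overall
}

#' Read review records from TSV
#'
#' Columns: `cnv_id`, `dosage_type`, `initial_labels`, `final_labels`
#' (comma-joined), `reasons` (comma-joined codes, may be empty/`.`),
#' `forced_review` (0/1).
#'
#' @param path TSV file
#' @return a [review_records()] data.frame
#' @export
read_review_records <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", "."))
  need <- c("cnv_id", "dosage_type", "initial_labels", "final_labels")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("review record table lacks column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  reasons <- as.character(df$reasons %||% "")
  reasons[is.na(reasons)] <- ""
  review_records(df$cnv_id, df$dosage_type, df$initial_labels,
                 df$final_labels, reasons,
                 forced_review = (df$forced_review %||% 0) %in%
                   c(1, "1", TRUE, "TRUE"))
}

#' Write a per-CNV scoring report
#'
#' @param score_results list of `score_result` objects
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_report <- function(score_results, path) {
  rows <- do.call(rbind, lapply(score_results, function(s) {
    data.frame(cnv_id = s$cnv_id,
               total_points = sprintf("%.2f", s$total_points),
               classification = s$classification,
               n_assignments = nrow(s$assignments),
               categories = paste(s$assignments$category_code,
                                  collapse = ","),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
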