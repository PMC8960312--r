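# shared fixture builders; everything is constructed in code at test time

# a small hand-laid annotation: known genes, a family, curated and
# uncurated dosage records, a benign region
tiny_annotation <- function() {
  genes <- data.frame(
    symbol = c("HIA", "FAM1", "FAM2", "FAM3", "SOLO", "FUNC", "JUNK"),
    chrom = c("1", "1", "1", "1", "1", "2", "2"),
    start = c(1e6, 5e6, 5.2e6, 5.4e6, 8e6, 1e6, 3e6),
    end = c(1.1e6, 5.1e6, 5.3e6, 5.5e6, 8.2e6, 1.2e6, 3.1e6),
    biotype = c(rep("protein_coding", 5), "other_functional_element",
                "other"),
    family_id = c(NA, "FAM", "FAM", "FAM", NA, NA, NA),
    stringsAsFactors = FALSE)
  regions <- data.frame(
    name = c("HIA", "TSB", "BENIGN1", "OMIM_SYN", "HIREG"),
    chrom = c("1", "2", "3", "1", "4"),
    start = c(1e6, 1e6, 1e6, 4e6, 1e6),
    end = c(1.1e6, 1.2e6, 9e6, 9e6, 4e6),
    role = c("HI_gene", "TS_gene", "benign_region", "HI_region",
             "HI_region"),
    curated = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  annotation_set(genes, regions)
}

one_cnv <- function(chrom, start, end, dosage_type = "loss", id = "c1") {
  cnv_panel(id, chrom, start, end, dosage_type = dosage_type)
}

# a dense single-chromosome gene grid for gene-count tests: n genes of
# 10 kb spaced every 100 kb from 1 Mb
gene_grid <- function(n, family = NULL) {
  start <- 1e6 + (seq_len(n) - 1) * 1e5
  annotation_set(data.frame(
    symbol = sprintf("GG%03d", seq_len(n)), chrom = "1",
    start = start, end = start + 1e4 - 1, biotype = "protein_coding",
    family_id = if (is.null(family)) NA_character_ else family,
    stringsAsFactors = FALSE))
}

# all 31 non-empty subsets of the five-tier labels
label_subsets <- function() {
  lv <- classification_levels()
  out <- list()
  for (k in 1:5) out <- c(out, combn(lv, k, simplify = FALSE))
  out
}

# independent oracle for conflict_class: worst pairwise conflict.
# Pairs are judged on management-group membership alone; the set's class
# is the most severe pairwise verdict.  A different computation path from
# the implementation's set-level rule.
oracle_conflict_class <- function(labels) {
  u <- unique(labels)
  if (length(u) == 1) return("complete")
  severity <- c(confidence_difference = 1, ror_impact = 2,
                management_impact = 3)
  pair_class <- function(a, b) {
    act <- c(P = "act", LP = "act", VUS = "vus", LB = "noact", B = "noact")
    ga <- act[[a]]; gb <- act[[b]]
    if (ga == gb) return("confidence_difference")
    if ("act" %in% c(ga, gb)) return("management_impact")
    "ror_impact"
  }
  worst <- "confidence_difference"
  for (i in seq_along(u)) for (j in seq_along(u)) {
    if (i < j) {
      pc <- pair_class(u[i], u[j])
      if (severity[pc] > severity[worst]) worst <- pc
    }
  }
  worst
}

# write a minimal SV VCF fixture
write_tiny_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##contig=<ID=17,length=81195210>",
    "##contig=<ID=2,length=243199373>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "17\t1551800\tdel17\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=2264023",
    "2\t1000000\tdup2\tN\t<DUP>\t.\tPASS\tSVTYPE=DUP;END=4000000",
    "2\t5000000\tinv2\tN\t<INV>\t.\tPASS\tSVTYPE=INV;END=5100000"),
    path)
  path
}

small_sim <- function(seed = 7, n_cnvs = 30, n_labs = 3, error_rates = numeric(0)) {
  cfg <- simulation_config(n_cnvs = n_cnvs, n_labs = n_labs,
                           error_rates = error_rates, seed = seed)
  ann <- generate_annotation(cfg)
  gen <- generate_panel(cfg, ann)
  list(cfg = cfg, ann = ann, panel = gen$panel, truth = gen$truth)
}
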