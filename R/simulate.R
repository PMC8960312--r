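# error modes the simulator can inject, a subset of the discordance
# reason vocabulary; modes marked needs_ann recompute evidence from the
# annotation set and require one
SIM_ERROR_MODES <- data.frame(
  code = c("S1_CONTENT_MISAPPLIED", "S2_PHENOTYPE_2J_2K",
           "S2_UNCURATED_SYNDROME", "S3_GENE_FAMILY",
           "S4_WEIGHT_UP_DOWN", "S4_CASE_DATA_USE"),
  needs_ann = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
  stringsAsFactors = FALSE)

# synthetic genome used by the generator: 4 autosome-sized chromosomes
SIM_CHROMS <- stats::setNames(rep(150e6, 4), as.character(1:4))

# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic per-(lab, cnv, mode) substream seed so that enabling one
# mode never shifts another mode's draws; kept below 2^31
.subseed <- function(seed, lab, cnv, mode) {
  (as.numeric(seed) * 2654435 + lab * 972663 + cnv * 40503 + mode * 2971) %%
    2147483647
}

#' Simulation configuration
#'
#' Captures the stated world the generator emulates: a multi-laboratory
#' proficiency panel.  Defaults mirror a distributed panel of 234 CNVs —
#' 77 nonrecurrent losses, 63 nonrecurrent gains and 47 recurrent CNVs
#' (each a matched loss/gain pair over the same interval, 94 calls), with
#' size-bin composition 77 / 127 / 22 / 8 for <1 Mb / 1-5 Mb / 5-10 Mb /
#' >10 Mb, classified by 9 laboratories.  Error kinds are documented but
#' their per-laboratory rates are not, so `error_rates` default to 0 and
#' are free parameters.
#'
#' @param n_cnvs total CNV calls in the panel
#' @param recurrent_fraction fraction of calls belonging to recurrent
#'   loss/gain pairs (94/234 by default)
#' @param loss_fraction_nonrecurrent fraction of nonrecurrent calls that
#'   are losses (77/140 by default)
#' @param size_distribution weights over the four [size_bins()], summing
#'   to 1
#' @param n_labs number of simulated laboratories
#' @param n_genes genes in the synthetic annotation (0 allowed)
#' @param error_rates named probabilities per lab per CNV for the
#'   injectable modes (see `sim_error_modes()`); unnamed modes are 0
#' @param seed mandatory integer seed
#' @return list of class `"sim_config"`
#' @export
simulation_config <- function(n_cnvs = 234,
                              recurrent_fraction = 94 / 234,
                              loss_fraction_nonrecurrent = 77 / 140,
                              size_distribution = c(77, 127, 22, 8) / 234,
                              n_labs = 9,
                              n_genes = 3600,
                              error_rates = numeric(0),
                              seed) {
  if (missing(seed) || is.null(seed)) abort("seed is mandatory")
  if (abs(sum(size_distribution) - 1) > 1e-6) {
    abort("size_distribution weights must sum to 1")
  }
  if (length(size_distribution) != 4) {
    abort("size_distribution needs one weight per size bin (4)")
  }
  rates <- stats::setNames(numeric(nrow(SIM_ERROR_MODES)),
                           SIM_ERROR_MODES$code)
  if (length(error_rates)) {
    bad <- setdiff(names(error_rates), SIM_ERROR_MODES$code)
    if (length(bad)) {
      abort(sprintf("unknown error mode(s): %s", paste(bad, collapse = ", ")))
    }
    if (any(error_rates < 0 | error_rates > 1)) {
      abort("error rates must be probabilities in [0, 1]")
    }
    rates[names(error_rates)] <- error_rates
  }
  structure(list(n_cnvs = n_cnvs, recurrent_fraction = recurrent_fraction,
                 loss_fraction_nonrecurrent = loss_fraction_nonrecurrent,
                 size_distribution = size_distribution, n_labs = n_labs,
                 n_genes = n_genes, error_rates = rates,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Names of the injectable simulator error modes
#' @return data.frame with `code` and `needs_ann`
#' @export
sim_error_modes <- function() SIM_ERROR_MODES

#' Generate a synthetic annotation set
#'
#' Builds a deterministic synthetic genome (4 chromosomes of 150 Mb) with
#' protein-coding genes at roughly the genome-wide density of 6 per Mb
#' (so gene-number bins are exercised by Mb-scale CNVs), a minority of
#' other-functional-element and non-functional features, gene families as
#' runs of adjacent paralogs, curated HI / TS genes and regions, curated
#' benign regions, and *uncurated* reported syndrome regions (the records
#' that must never be auto-applied as established evidence).
#'
#' @param config a [simulation_config()]
#' @param seed RNG seed (defaults to `config$seed`)
#' @return an [annotation_set()]
#' @export
generate_annotation <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    ng <- config$n_genes
    genes <- NULL
    if (ng > 0) {
      chrom <- sample(names(SIM_CHROMS), ng, replace = TRUE,
                      prob = SIM_CHROMS / sum(SIM_CHROMS))
      len <- pmin(pmax(round(stats::rlnorm(ng, log(3e4), 0.8)), 200), 2e6)
      start <- floor(stats::runif(ng, 1, SIM_CHROMS[chrom] - len))
      biotype <- sample(c("protein_coding", "other_functional_element",
                          "other"), ng, replace = TRUE,
                        prob = c(0.92, 0.04, 0.04))
      genes <- data.frame(symbol = sprintf("G%04d", seq_len(ng)),
                          chrom = chrom, start = start,
                          end = start + len - 1, biotype = biotype,
                          family_id = NA_character_,
                          stringsAsFactors = FALSE)
      # families: runs of adjacent genes on one chromosome share an id
      genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
      n_fam <- max(0, round(ng * 0.03))
      for (f in seq_len(n_fam)) {
        anchor <- sample(ng, 1)
        size <- sample(3:8, 1)
        idx <- anchor:min(anchor + size - 1, ng)
        idx <- idx[genes$chrom[idx] == genes$chrom[anchor] &
                   is.na(genes$family_id[idx])]
        genes$family_id[idx] <- sprintf("FAM%03d", f)
      }
    }
    rand_region <- function(n, min_len, max_len) {
      chrom <- sample(names(SIM_CHROMS), n, replace = TRUE)
      len <- floor(stats::runif(n, min_len, max_len))
      start <- floor(stats::runif(n, 1, SIM_CHROMS[chrom] - len))
      data.frame(chrom = chrom, start = start, end = start + len - 1,
                 stringsAsFactors = FALSE)
    }
    gene_region <- function(n, role) {
      if (is.null(genes)) return(NULL)
      pc <- genes[genes$biotype == "protein_coding", , drop = FALSE]
      pick <- pc[sample(nrow(pc), min(n, nrow(pc))), , drop = FALSE]
      data.frame(name = pick$symbol, chrom = pick$chrom,
                 start = pick$start, end = pick$end, role = role,
                 curated = TRUE, stringsAsFactors = FALSE)
    }
    mk <- function(n, role, curated, min_len = 5e5, max_len = 3e6) {
      r <- rand_region(n, min_len, max_len)
      data.frame(name = sprintf("%s_%02d", role, seq_len(n)),
                 chrom = r$chrom, start = r$start, end = r$end,
                 role = role, curated = curated, stringsAsFactors = FALSE)
    }
    regions <- rbind(
      gene_region(25, "HI_gene"), gene_region(15, "TS_gene"),
      mk(8, "HI_region", TRUE), mk(5, "TS_region", TRUE),
      mk(12, "benign_region", TRUE, 1e6, 4e6),
      # reported syndrome regions never dosage-curated: flag-only
      mk(10, "HI_region", FALSE, 1e6, 5e6))
    annotation_set(genes, regions)
  })
}

#' Generate a CNV panel and its truth worksheets
#'
#' Draws CNV sizes from the configured bin weights (uniform within bin),
#' places them uniformly on the synthetic genome, and emits recurrent
#' calls as matched loss/gain pairs over the identical interval.  The
#' truth worksheet per call is the deterministic Sections 1-3 evidence
#' from [auto_worksheet()] plus sampled Section-4 case evidence at the
#' rubric defaults (Section 4 is what real laboratories mine from
#' literature and databases; the simulator samples it so the panel spans
#' the five classes).
#'
#' @param config a [simulation_config()]
#' @param ann an [annotation_set()], e.g. from [generate_annotation()]
#' @param seed RNG seed (defaults to `config$seed`)
#' @return list with `panel` (a [cnv_panel()]), `truth` (worksheet
#'   data.frame: cnv_id, lab_id = "truth", category_code, points,
#'   justification, provenance), `flags` (character)
#' @export
generate_panel <- function(config, ann, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), inherits(ann, "annotation_set"))
  rubrics <- list(loss = load_rubric("loss"), gain = load_rubric("gain"))
  with_seed(seed, {
    n <- config$n_cnvs
    n_pairs <- floor(n * config$recurrent_fraction / 2)
    n_nonrec <- n - 2 * n_pairs
    n_loss <- round(n_nonrec * config$loss_fraction_nonrecurrent)
    n_intervals <- n_pairs + n_nonrec
    bin_edges <- list(c(5e4, 1e6 - 1), c(1e6, 5e6 - 1),
                      c(5e6, 1e7), c(1e7 + 1, 2e7))
    bin <- sample(4, n_intervals, replace = TRUE,
                  prob = config$size_distribution)
    len <- vapply(bin, function(b) {
      floor(stats::runif(1, bin_edges[[b]][1], bin_edges[[b]][2] + 1))
    }, numeric(1))
    chrom <- sample(names(SIM_CHROMS), n_intervals, replace = TRUE,
                    prob = SIM_CHROMS / sum(SIM_CHROMS))
    start <- floor(stats::runif(n_intervals, 1, SIM_CHROMS[chrom] - len))
    is_pair <- seq_len(n_intervals) <= n_pairs
    idx <- c(rep(which(is_pair), each = 2), which(!is_pair))
    dosage <- c(rep(c("loss", "gain"), n_pairs),
                rep("loss", n_loss), rep("gain", n_nonrec - n_loss))
    panel <- cnv_panel(
      id = sprintf("sim%03d_%s", idx, substr(dosage, 1, 1)),
      chrom = chrom[idx], start = start[idx], end = start[idx] + len[idx] - 1,
      dosage_type = dosage,
      copy_number = ifelse(dosage == "loss", 1L, 3L),
      recurrent = rep(c(TRUE, FALSE), c(2 * n_pairs, n_nonrec)))
    s4_pool <- c("4A", "4B", "4C", "4E", "4L", "4O", "4N")
    truth <- vector("list", nrow(panel))
    flags <- character(0)
    for (i in seq_len(nrow(panel))) {
      cnv <- panel[i, ]
      rb <- rubrics[[cnv$dosage_type]]
      aw <- auto_worksheet(cnv, ann, rb)
      flags <- c(flags, aw$flags)
      k <- sample(0:3, 1, prob = c(0.35, 0.3, 0.25, 0.1))
      a <- aw$assignments
      if (k > 0) {
        codes <- sample(s4_pool, k)
        pts <- vapply(codes, function(cd) {
          rubric_category(rb, cd)$default_points
        }, numeric(1))
        a <- rbind(a, ev_assign(codes, pts, "sampled case evidence",
                                provenance = "manual"))
      }
      a$cnv_id <- cnv$id
      a$lab_id <- "truth"
      truth[[i]] <- a
    }
    truth <- do.call(rbind, truth)
    truth <- truth[, c("cnv_id", "lab_id", "category_code", "points",
                       "justification", "provenance")]
    rownames(truth) <- NULL
    list(panel = panel, truth = truth, flags = flags)
  })
}

# apply one error mode to a single-CNV worksheet; assignments df in/out
.apply_mode <- function(mode, a, cnv, ann, rubric) {
  s4 <- which(substr(a$category_code, 1, 1) == "4")
  switch(mode,
    S1_CONTENT_MISAPPLIED = {
      i <- which(a$category_code %in% c("1A", "1B"))
      if (length(i) == 1) {
        flip <- if (a$category_code[i] == "1A") "1B" else "1A"
        a$category_code[i] <- flip
        a$points[i] <- rubric_category(rubric, flip)$default_points
      }
      a
    },
    S2_PHENOTYPE_2J_2K = {
      i <- which(a$category_code %in% c("2J", "2K"))
      if (length(i) == 1) {
        swap <- if (a$category_code[i] == "2J") "2K" else "2J"
        a$category_code[i] <- swap
        a$points[i] <- rubric_category(rubric, swap)$default_points
      }
      a
    },
    S2_UNCURATED_SYNDROME = {
      # the documented misuse: an uncurated reported syndrome region is
      # applied as if established (2A)
      r <- regions_in(cnv, ann)
      r <- r[!r$curated, , drop = FALSE]
      if (nrow(r) > 0 && !("2A" %in% a$category_code)) {
        a <- rbind(a, ev_assign("2A", rubric_category(rubric, "2A")$default_points,
                                sprintf("uncurated region '%s' misused as established",
                                        r$name[1]),
                                provenance = "manual"))
      }
      a
    },
    S3_GENE_FAMILY = {
      i <- which(substr(a$category_code, 1, 1) == "3")
      if (length(i) == 1) {
        repl <- assign_section3(cnv, ann, rubric, collapse_families = TRUE)
        a$category_code[i] <- repl$category_code
        a$points[i] <- repl$points
        a$justification[i] <- repl$justification
      }
      a
    },
    S4_WEIGHT_UP_DOWN = {
      if (length(s4) > 0) {
        i <- s4[sample(length(s4), 1)]
        step <- sample(c(-0.15, 0.15), 1)
        cat_row <- rubric_category(rubric, a$category_code[i])
        a$points[i] <- min(max(a$points[i] + step, cat_row$min_points),
                           cat_row$max_points)
      }
      a
    },
    S4_CASE_DATA_USE = {
      if (length(s4) > 0) {
        a <- a[-s4[sample(length(s4), 1)], , drop = FALSE]
      }
      a
    },
    abort(sprintf("unknown error mode '%s'", mode)))
}

#' Simulate per-laboratory classifications
#'
#' Every laboratory starts from the truth worksheet of every CNV and
#' independently applies each enabled error mode as a Bernoulli event
#' with its configured probability; the perturbed worksheet is then
#' scored and classified with the matching rubric.  Random streams are
#' split per (laboratory, CNV, mode), so enabling one mode never shifts
#' another mode's draws, and the whole matrix is bit-identical under a
#' fixed seed.  With all rates at 0 the output is the truth
#' classification at every laboratory (complete concordance everywhere).
#'
#' @param panel,truth output of [generate_panel()]
#' @param config a [simulation_config()] (supplies `n_labs`,
#'   `error_rates`)
#' @param seed RNG seed (defaults to `config$seed`)
#' @param ann the [annotation_set()]; required if any enabled mode has
#'   `needs_ann` (see [sim_error_modes()])
#' @return a [classification_matrix()] with per-CNV metadata
#' @export
simulate_lab_classifications <- function(panel, truth, config,
                                         seed = config$seed, ann = NULL) {
  stopifnot(inherits(config, "sim_config"))
  rates <- config$error_rates
  active <- names(rates)[rates > 0]
  need <- SIM_ERROR_MODES$code[SIM_ERROR_MODES$needs_ann]
  if (length(intersect(active, need)) && is.null(ann)) {
    abort(sprintf("error mode(s) %s require an annotation set",
                  paste(intersect(active, need), collapse = ", ")))
  }
  missing_truth <- setdiff(panel$id, unique(truth$cnv_id))
  if (length(missing_truth)) {
    abort(sprintf("truth worksheet missing CNV(s): %s",
                  paste(missing_truth, collapse = ", ")))
  }
  rubrics <- list(loss = load_rubric("loss"), gain = load_rubric("gain"))
  labs <- sprintf("lab%02d", seq_len(config$n_labs))
  cells <- matrix(NA_character_, nrow(panel), config$n_labs,
                  dimnames = list(panel$id, labs))
  mode_idx <- stats::setNames(seq_along(rates), names(rates))
  truth_split <- split(truth, truth$cnv_id)
  for (ci in seq_len(nrow(panel))) {
    cnv <- panel[ci, ]
    rb <- rubrics[[cnv$dosage_type]]
    base <- truth_split[[cnv$id]]
    base <- base[, c("category_code", "points", "justification",
                     "provenance")]
    for (li in seq_len(config$n_labs)) {
      a <- base
      for (m in active) {
        # promise evaluation happens in this frame, so `a` updates in place
        with_seed(.subseed(seed, li, ci, mode_idx[[m]]), {
          if (stats::runif(1) < rates[[m]]) {
            a <- .apply_mode(m, a, cnv, ann, rb)
          }
        })
      }
      cells[ci, li] <- score_cnv(cnv, a, rb)$classification
    }
  }
  meta <- data.frame(cnv_id = panel$id, dosage_type = panel$dosage_type,
                     recurrent = panel$recurrent, panel = "distributed",
                     phase = "metric", stringsAsFactors = FALSE)
  classification_matrix(cells, meta)
}
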