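# cnvconcord

Point-based scoring and inter-laboratory concordance analysis for
clinical copy-number variant (CNV) classification.

Clinical laboratories classify CNVs (deletions and duplications) on the
five-tier scale **P / LP / VUS / LB / B** using the ACMG-ClinGen
semiquantitative point-based metric: evidence categories in five sections
(genomic content; dosage sensitivity; gene number; case, database and
case-control evidence; inheritance and family history) contribute signed
points; the summed total *t* is thresholded

> t ≥ 0.99 → P,  0.90 ≤ t < 0.99 → LP,  −0.90 < t < 0.90 → VUS,
> −0.99 < t ≤ −0.90 → LB,  t ≤ −0.99 → B.

When several laboratories classify the same CNV, their label pattern is
judged with a conflict-severity taxonomy: **complete** concordance;
**confidence difference** (P vs LP, or LB vs B — same clinical action);
conflict impacting **return of results** (VUS vs LB/B); conflict
impacting **medical management** (P/LP vs VUS/LB/B).

`cnvconcord` is for laboratories and proficiency-scheme organisers
running such multi-laboratory comparisons. It provides:

* `genome_model` — 1-based inclusive interval arithmetic
  (`gintv`, `overlap_bp`, `gi_contains`), CNV panels with size bins
  (`cnv_panel`, `size_class`), annotation sets and gene/region queries
  (`annotation_set`, `genes_in`, `regions_in`);
* `rubric_scoring` — editable JSON rubrics (`load_rubric`,
  `write_rubric`), validation (`validate_assignment`), summation and
  classification (`total_score`, `classify`, `score_cnv`);
* `auto_evidence` — deterministic Sections 1–3 assignment
  (`assign_section1/2/3`, `auto_worksheet`) with review flags for
  partial overlaps and uncurated dosage records;
* `concordance` — the taxonomy (`conflict_class`), matrix summaries
  (`summarize_concordance`), pattern tallies (`partition_counts`) and
  Pearson chi-square rate comparison (`compare_rates`);
* `discordance_audit` — re-review bookkeeping (`review_records`,
  `tabulate_review`, `reason_summary`);
* `synthetic_data` — a deterministic panel/laboratory simulator with
  injectable error modes (`simulation_config`, `generate_annotation`,
  `generate_panel`, `simulate_lab_classifications`);
* a CLI (`run_cli`) with `classify | score | concord | audit | simulate`
  subcommands.

## Worked example

The package bundles the re-review pattern table of a nine-laboratory
comparison: 82 initially discordant CNVs (39 deletions, 43 duplications)
plus one deletion re-reviewed despite complete initial VUS concordance.

```r
library(cnvconcord)

pat <- example_review_patterns()
agg <- aggregate(count ~ initial_labels, pat[!pat$forced_review, ], sum)
partition_counts(data.frame(labels = agg$initial_labels, count = agg$count))
#>              complete confidence_difference            ror_impact
#>                     0                    10                    16
#>     management_impact
#>                    56
```

Of the 82 initially discordant CNVs, 56 conflicts could impact medical
management, 16 could impact return of results, and 10 are P-vs-LP
confidence differences. Re-review tabulation:

```r
tab <- tabulate_review(expand_review_patterns(pat))
tab$totals
#>  dosage_type  n n_resolved n_discordant
#>         loss 40         13           27
#>         gain 43         21           22
print(tab)   # ...
#> final complete concordance: 41% (34/83); final management-impacting: 42% (35/83)
```

(The loss row counts 40 because it includes the forced-review deletion;
excluding it with `include_forced = FALSE` gives the 39/13/26 deletion
and 43/21/22 duplication totals.) 34 of the 83 re-reviewed CNVs reached
final complete concordance, and 35 (42%) remained discordant in a way
that could impact management. Rate comparisons use the Pearson
chi-square without continuity correction:

```r
cr <- compare_rates(41, 234, 177, 234)   # 18% vs 76% complete concordance
sprintf("chi-square = %.2f, p = %.2g, significant: %s",
        cr$statistic, cr$p_value, cr$significant)
#> "chi-square = 158.83, p = 2e-36, significant: TRUE"
```

Simulating a panel end to end:

```r
cfg <- simulation_config(n_cnvs = 60, n_labs = 9, seed = 7,
                         error_rates = c(S2_PHENOTYPE_2J_2K = 0.2,
                                         S4_WEIGHT_UP_DOWN = 0.1))
ann <- generate_annotation(cfg)
gen <- generate_panel(cfg, ann)
m   <- simulate_lab_classifications(gen$panel, gen$truth, cfg, ann = ann)
summarize_concordance(m)
```

## Vignette

`vignettes/cnv-scoring-and-concordance.Rmd` documents the scoring model
and thresholds, the automatic-evidence rules and their edge conventions,
the taxonomy's severity precedence, what the simulator does and does not
emulate, and known limitations.
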