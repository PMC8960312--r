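---
title: "Point-based CNV classification and inter-laboratory concordance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-based CNV classification and inter-laboratory concordance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvconcord)
```

## The problem

Clinical laboratories must assign one of five classifications — pathogenic
(P), likely pathogenic (LP), uncertain significance (VUS), likely benign
(LB), benign (B) — to each copy-number variant (CNV) they report.  The
ACMG-ClinGen technical standards replace free-form judgement with a
semiquantitative point-based metric: evidence is organised into five
sections (1 genomic content; 2 dosage sensitivity; 3 gene number;
4 literature / database / case-control evidence; 5 inheritance and family
history), each applied category contributes signed points, and the summed
total is thresholded into the five tiers.  Even so, laboratories continue
to disagree, and multi-laboratory comparison exercises need a precise
vocabulary for *how badly* they disagree and bookkeeping for *why*.

`cnvconcord` implements both halves: a configurable rubric engine that
scores CNV evidence worksheets, and the concordance/audit machinery that
classifies multi-laboratory disagreement patterns, tabulates re-review
rounds, and compares rates.

## The scoring model

A **rubric** is a data-driven table (JSON under
`system.file("extdata", package = "cnvconcord")`), one per dosage type
(loss = deletion, gain = duplication).  Each category carries a default,
a minimum and a maximum point value; evaluators may move within the range
(the standards allow up- and down-weighting), never outside it.  The
total is the plain sum of the applied points — no caps, no interactions —
and classification is a monotone step function of the total:

| total *t* | class |
|---|---|
| *t* ≥ 0.99 | P |
| 0.90 ≤ *t* < 0.99 | LP |
| −0.90 < *t* < 0.90 | VUS |
| −0.99 < *t* ≤ −0.90 | LB |
| *t* ≤ −0.99 | B |

An empty worksheet therefore classifies as VUS, the centre of the scale.

Two point values in the shipped gain rubric are anchored directly in the
multi-laboratory comparison this package models: category 2K (a gain
breakpoint inside an established haploinsufficient gene, patient
phenotype specific and consistent) is worth 0.45 points and category 2J
(same breakpoint observation, phenotype nonspecific or inconsistent) is
worth 0.  Every other number in the shipped tables is encoded from the
2020 technical standard the comparison applied; because those values are
not independently verifiable from the comparison itself, the rubric is
deliberately *configuration, not code* — `load_rubric(config =)` accepts
an edited JSON file and validates it (unique codes, ordered ranges, all
five sections, exactly one Section-1 pair, ordered thresholds).

Numerical choices: point-range checks use absolute tolerance 1e−9;
totals are displayed to 2 decimals but classified unrounded; 2J and 2K
are mutually exclusive on one worksheet (they are competing readings of
the same breakpoint observation); at most one assignment per category
per CNV.

## Automatic evidence (Sections 1–3)

Sections 1–3 are functions of the CNV interval and an annotation set, and
the decision points known to cause inter-laboratory discordance are
implemented as explicit, mechanical rules:

* **Section 1** is total: 1A iff the CNV overlaps ≥ 1 protein-coding gene
  or other known functionally important element, else 1B.
* **Section 2** applies only *established* (curated) records.  Complete
  containment of an established HI/TS gene or region ⇒ 2A; complete
  containment of the CNV inside an established benign region ⇒ the
  benign-containment category (2F loss / 2D gain); a gain breakpoint
  inside an established HI gene ⇒ 2K, a gain merely spanning it ⇒ 2J
  (never both; 2K wins when both observations exist).  **Partial**
  overlap of a dosage region and **uncurated** records (e.g. reported
  syndrome regions never formally dosage-curated) yield a review flag and
  zero points — the documented error mode is exactly their unreviewed
  promotion to 2A, so the engine refuses to guess.
* **Section 3** counts protein-coding genes and looks the count up in the
  rubric's bins (loss: 0–24 / 25–34 / ≥ 35; gain: 0–34 / 35–49 / ≥ 50).
  `collapse_families = TRUE` counts a gene family once, reproducing the
  "one gene or many" ambiguity; it is off by default.

A breakpoint "inside" a gene includes the gene's boundary coordinates:
single-base breakpoint resolution of clinical calls is unreliable, so an
exact-boundary call is treated as disrupting the gene.  This convention
is a package choice; the source comparisons do not define the case.

Sections 4 and 5 are never automated — case curation is a human
literature exercise — and enter only through evidence worksheets.

## The conflict-severity taxonomy

For one CNV classified by several laboratories, the label multiset is
mapped to exactly one of four classes, in decreasing severity:
`management_impact` (P or LP vs any of VUS/LB/B — treatment could
change), `ror_impact` (VUS vs LB/B — return-of-result could change),
`confidence_difference` (P vs LP, or LB vs B — same clinical
recommendation), `complete` (all identical).  For sets spanning three
groups (e.g. {P, VUS, LB}) severity precedence management > ROR >
confidence applies; this precedence is the only reading that reproduces
the published pattern tallies (the "P or LP vs. VUS vs. LB or B" rows
count as management conflicts), which is its justification.  The
taxonomy is brute-force verified against an independent pairwise oracle
over all 31 non-empty label subsets in the test suite.

Percentages in reports are integer round-half-up next to the exact
fraction ("76% (177/234)"), matching how such rates are printed in the
field.  Rate differences use the Pearson chi-square on the 2×2 table
without continuity correction (the source analyses name only "chi-square
test", and no correction reproduces their significance calls), erroring
when an expected cell is zero rather than silently approximating.

## Re-review audit

`review_records` hold one row per re-evaluated CNV: initial pattern,
final pattern, reason tags from a closed 16-code vocabulary keyed to
rubric sections.  Patterns are label *sets* — order- and
multiplicity-insensitive — because published tables report "P or VUS"
rows, not per-laboratory detail.  An initially concordant record is only
admitted with `forced_review = TRUE` (a panel may re-review a fully
concordant call that central scoring suggests is wrong; the bundled
example contains one such deletion, finally discordant P vs VUS).
Reason tags are tallied verbatim and never inferred from score diffs:
the attribution exercise they model was a manual consensus process.
`reason_summary` buckets records by the exact set of sections implicated
("Section 4 alone", "Section 2 + Section 4", ...), a partition of the
records.

The package ships `example_review_patterns()`, the re-review pattern
table of a published nine-laboratory comparison (82 discordant CNVs:
39 deletions and 43 duplications, plus the forced-review deletion).  The
tests and the acceptance script recompute from it: the 56 / 16 / 10
partition of initial patterns into management / ROR / confidence
conflicts; deletion totals (39, 13 resolved, 26 still discordant) and
duplication totals (43, 21, 22); 34 CNVs reaching final complete
concordance; and 35/83 → 42% finally management-impacting.

## What the simulator states, and what a green test establishes

`simulation_config()` defaults *are* the emulated world: 234 CNV calls —
77 nonrecurrent losses, 63 nonrecurrent gains, 47 recurrent loss/gain
pairs (94 calls) — with size-bin weights 77/127/22/8 over <1 Mb, 1–5 Mb,
5–10 Mb, >10 Mb, classified by 9 laboratories.  The synthetic genome is
4 chromosomes × 150 Mb with protein-coding genes at ~6 per Mb (the
genome-wide average, so Mb-scale CNVs exercise the Section-3 bins),
gene families as runs of adjacent paralogs, curated HI/TS and benign
regions, and uncurated syndrome regions.  Where the sources state no
value (gene density, region counts, within-bin size law, Section-4
sampling) the defaults were chosen once on field realism and are not
tuned to any output.

Error modes mirror documented error kinds — 1A/1B inversion, 2J↔2K
swap, uncurated-region promotion to 2A, family collapsing, ±0.15
Section-4 weight steps (clipped to the category range; one worksheet
"step" chosen to straddle the LP/VUS boundary in plausible worksheets),
dropped Section-4 evidence — as independent per-(laboratory, CNV)
Bernoulli events.  Their *rates* are free parameters: per-laboratory
accuracies were never published, so the simulator makes no attempt to
reproduce the published 18% → 76% concordance trajectory, and no test
asserts it.  RNG streams are split per (laboratory, CNV, mode) so
enabling one mode never shifts another's draws.

A green simulation test therefore establishes internal consistency —
determinism, the zero-noise identity, confinement of each error mode to
its footprint — not fidelity to any real laboratory's behaviour.  Real
panels differ in ways the generator does not model: CNVs are chosen to
tile interesting loci rather than uniformly, evidence availability
correlates with locus recurrence, laboratories are not exchangeable, and
Section-4/5 evidence has structure (shared literature) that independent
sampling ignores.

## Degenerate inputs and edge conventions

1-based inclusive coordinates everywhere; BED converted at the I/O
boundary, GFF3 passed through; adjacent-touching intervals share 1 bp.
`chr` prefixes stripped case-insensitively; builds carried but never
lifted over, and mixed builds in one panel are an error.  Size-bin
boundaries: exactly 1 Mb → "1-5 Mb", exactly 5 and 10 Mb → "5-10 Mb"
(the published bins print no boundary rule; this is a package
convention).  Laboratories with no call for a CNV are dropped from that
row only, defensively.  The one known internal inconsistency in the
published aggregate arithmetic (224 + 34 − 1 ≠ 260) is left as printed:
each figure is reproduced from its own stated inputs, and the package
does not attempt to reconcile them.

## Known limitations

* Sections 4–5 are worksheet-only by design; no literature or database
  mining.
* No liftover, no cytoband parsing (band labels are free-text metadata).
* The shipped rubric encodes the 2020 standard's values but is not a
  certified copy of it; treat it as an editable starting point.
* No chance-corrected agreement coefficients (kappa): the modelled
  analyses use only the rate taxonomy plus chi-square.
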