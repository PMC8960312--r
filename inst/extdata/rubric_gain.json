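{
  "dosage_type": "gain",
  "thresholds": { "p_min": 0.99, "lp_min": 0.90, "lb_max": -0.90, "b_max": -0.99 },
  "exclusive": [ ["2J", "2K"] ],
  "categories": [
    { "code": "1A", "section": 1, "default": 0.0, "min": 0.0, "max": 0.0,
      "description": "Contains protein-coding genes or other known functionally important elements" },
    { "code": "1B", "section": 1, "default": -0.6, "min": -0.6, "max": -0.6,
      "description": "Does NOT contain protein-coding genes or any known functionally important elements" },
    { "code": "2A", "section": 2, "default": 1.0, "min": 1.0, "max": 1.0,
      "description": "Complete containment of an established triplosensitive (TS) gene or genomic region" },
    { "code": "2B", "section": 2, "default": 0.0, "min": 0.0, "max": 0.0,
      "description": "Partial overlap of an established TS genomic region" },
    { "code": "2C", "section": 2, "default": -1.0, "min": -1.0, "max": -1.0,
      "description": "Identical in gene content to an established benign copy-number gain" },
    { "code": "2D", "section": 2, "default": -1.0, "min": -1.0, "max": 0.0,
      "description": "Smaller than an established benign gain; breakpoints do not interrupt protein-coding genes" },
    { "code": "2E", "section": 2, "default": 0.0, "min": 0.0, "max": 0.0,
      "description": "Smaller than an established benign gain; breakpoints potentially interrupt protein-coding genes" },
    { "code": "2F", "section": 2, "default": -1.0, "min": -1.0, "max": 0.0,
      "description": "Larger than an established benign gain; no additional protein-coding genes" },
    { "code": "2G", "section": 2, "default": 0.0, "min": 0.0, "max": 0.0,
      "description": "Overlaps an established benign gain but includes additional genomic material" },
    { "code": "2H", "section": 2, "default": 0.0, "min": 0.0, "max": 0.0,
      "description": "An established HI gene is fully contained within the gain (dosage of the HI gene is increased, not reduced)" },
    { "code": "2I", "section": 2, "default": 0.0, "min": 0.0, "max": 0.9,
      "description": "Both breakpoints within the same established HI gene; loss-of-function assessment applies" },
    { "code": "2J", "section": 2, "default": 0.0, "min": 0.0, "max": 0.45,
      "description": "One breakpoint within an established HI gene; patient phenotype inconsistent with or nonspecific for that gene" },
    { "code": "2K", "section": 2, "default": 0.45, "min": 0.45, "max": 0.45,
      "description": "One breakpoint within an established HI gene; patient phenotype highly specific and consistent with disruption of that gene" },
    { "code": "2L", "section": 2, "default": 0.0, "min": 0.0, "max": 0.45,
      "description": "One breakpoint within any other (non-established) gene" },
    { "code": "3A", "section": 3, "default": 0.0, "min": 0.0, "max": 0.0,
      "count_min": 0, "count_max": 34,
      "description": "0-34 protein-coding genes within the gain" },
    { "code": "3B", "section": 3, "default": 0.45, "min": 0.45, "max": 0.45,
      "count_min": 35, "count_max": 49,
      "description": "35-49 protein-coding genes within the gain" },
    { "code": "3C", "section": 3, "default": 0.9, "min": 0.9, "max": 0.9,
      "count_min": 50, "count_max": null,
      "description": "50 or more protein-coding genes within the gain" },
    { "code": "4A", "section": 4, "default": 0.45, "min": 0.0, "max": 0.45,
      "description": "Reported proband with a highly specific, relatively unique phenotype consistent with the gene/region; confirmed de novo" },
    { "code": "4B", "section": 4, "default": 0.3, "min": 0.0, "max": 0.45,
      "description": "Reported proband with a highly specific but not unique phenotype; confirmed de novo" },
    { "code": "4C", "section": 4, "default": 0.15, "min": 0.0, "max": 0.3,
      "description": "Reported proband with a consistent but not highly specific phenotype; confirmed de novo" },
    { "code": "4D", "section": 4, "default": 0.0, "min": 0.0, "max": 0.15,
      "description": "Reported proband with a nonspecific phenotype; confirmed de novo" },
    { "code": "4E", "section": 4, "default": 0.1, "min": 0.0, "max": 0.3,
      "description": "Reported proband with a consistent phenotype; unknown inheritance" },
    { "code": "4F", "section": 4, "default": 0.15, "min": 0.0, "max": 0.15,
      "description": "3-4 observed segregations with a consistent phenotype" },
    { "code": "4G", "section": 4, "default": 0.3, "min": 0.0, "max": 0.3,
      "description": "5-6 observed segregations with a consistent phenotype" },
    { "code": "4H", "section": 4, "default": 0.45, "min": 0.0, "max": 0.45,
      "description": "7 or more observed segregations with a consistent phenotype" },
    { "code": "4I", "section": 4, "default": -0.45, "min": -0.45, "max": 0.0,
      "description": "Non-segregation observed in multiple families" },
    { "code": "4J", "section": 4, "default": -0.3, "min": -0.3, "max": 0.0,
      "description": "Non-segregation observed in one family" },
    { "code": "4K", "section": 4, "default": -0.15, "min": -0.15, "max": 0.0,
      "description": "Single non-segregation with atypical phenotypic assessment" },
    { "code": "4L", "section": 4, "default": 0.45, "min": 0.0, "max": 0.45,
      "description": "Statistically significant increase among observations in cases versus controls" },
    { "code": "4M", "section": 4, "default": 0.3, "min": 0.0, "max": 0.45,
      "description": "Statistically significant increase among observations in cases (no controls)" },
    { "code": "4N", "section": 4, "default": -0.9, "min": -0.9, "max": 0.0,
      "description": "No statistically significant difference between cases and controls" },
    { "code": "4O", "section": 4, "default": -1.0, "min": -1.0, "max": 0.0,
      "description": "Overlap with common population variation (frequency at or above 1%)" },
    { "code": "5A", "section": 5, "default": 0.0, "min": 0.0, "max": 0.45,
      "description": "Inheritance information for the patient is unavailable or uninformative" },
    { "code": "5B", "section": 5, "default": 0.3, "min": 0.0, "max": 0.45,
      "description": "Patient with a specific, well-defined phenotype; CNV confirmed de novo" },
    { "code": "5C", "section": 5, "default": 0.15, "min": 0.0, "max": 0.3,
      "description": "Patient with a nonspecific phenotype; CNV confirmed de novo" },
    { "code": "5D", "section": 5, "default": 0.3, "min": 0.0, "max": 0.45,
      "description": "CNV segregates with a consistent phenotype in the patient's family" },
    { "code": "5E", "section": 5, "default": -0.45, "min": -0.45, "max": 0.0,
      "description": "Non-segregation observed in the patient's family" },
    { "code": "5F", "section": 5, "default": 0.0, "min": -0.45, "max": 0.0,
      "description": "Inherited from an apparently unaffected parent" },
    { "code": "5G", "section": 5, "default": 0.1, "min": 0.0, "max": 0.15,
      "description": "Inherited; a parent shows a consistent but milder phenotype" },
    { "code": "5H", "section": 5, "default": 0.0, "min": -0.3, "max": 0.3,
      "description": "Region subject to imprinting or documented reduced penetrance; inheritance evidence reweighted accordingly" }
  ]
}
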