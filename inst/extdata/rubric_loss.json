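{
  "dosage_type": "loss",
  "thresholds": { "p_min": 0.99, "lp_min": 0.90, "lb_max": -0.90, "b_max": -0.99 },
  "exclusive": [],
  "categories": [
    { "code": "1A", "section": 1, "default": 0.0, "min": 0.0, "max": 0.0,
      "description": "Contains protein-coding genes or other known functionally important elements" },
    { "code": "1B", "section": 1, "default": -0.6, "min": -0.6, "max": -0.6,
      "description": "Does NOT contain protein-coding genes or any known functionally important elements" },
    { "code": "2A", "section": 2, "default": 1.0, "min": 1.0, "max": 1.0,
      "description": "Complete overlap of an established haploinsufficient (HI) gene or genomic region" },
    { "code": "2B", "section": 2, "default": 0.0, "min": 0.0, "max": 0.0,
      "description": "Partial overlap of an established HI genomic region" },
    { "code": "2C-1", "section": 2, "default": 0.9, "min": 0.45, "max": 1.0,
      "description": "Partial overlap with the 5' end of an established HI gene; coding sequence involved" },
    { "code": "2C-2", "section": 2, "default": 0.0, "min": 0.0, "max": 0.45,
      "description": "Partial overlap with the 5' end of an established HI gene; only the 5' UTR involved" },
    { "code": "2D-1", "section": 2, "default": 0.0, "min": 0.0, "max": 0.0,
      "description": "Partial overlap with the 3' end of an established HI gene; only the 3' UTR involved" },
    { "code": "2D-2", "section": 2, "default": 0.9, "min": 0.45, "max": 0.9,
      "description": "Partial overlap with the 3' end of an established HI gene; only the last exon involved, with established pathogenic variants in that exon" },
    { "code": "2D-3", "section": 2, "default": 0.3, "min": 0.0, "max": 0.45,
      "description": "Partial overlap with the 3' end of an established HI gene; only the last exon involved, no established pathogenic variants" },
    { "code": "2D-4", "section": 2, "default": 0.9, "min": 0.45, "max": 1.0,
      "description": "Partial overlap with the 3' end of an established HI gene; exons in addition to the last exon involved, nonsense-mediated decay expected" },
    { "code": "2E", "section": 2, "default": 0.9, "min": 0.0, "max": 0.9,
      "description": "Both breakpoints within the same gene; loss-of-function assessment applies" },
    { "code": "2F", "section": 2, "default": -1.0, "min": -1.0, "max": -1.0,
      "description": "Completely contained within an established benign CNV region" },
    { "code": "2G", "section": 2, "default": 0.0, "min": 0.0, "max": 0.0,
      "description": "Overlaps an established benign CNV region but includes additional genomic material" },
    { "code": "2H", "section": 2, "default": 0.15, "min": 0.0, "max": 0.15,
      "description": "Two or more HI predictors suggest at least one gene in the interval is haploinsufficient" },
    { "code": "3A", "section": 3, "default": 0.0, "min": 0.0, "max": 0.0,
      "count_min": 0, "count_max": 24,
      "description": "0-24 protein-coding genes within the loss" },
    { "code": "3B", "section": 3, "default": 0.45, "min": 0.45, "max": 0.45,
      "count_min": 25, "count_max": 34,
      "description": "25-34 protein-coding genes within the loss" },
    { "code": "3C", "section": 3, "default": 0.9, "min": 0.9, "max": 0.9,
      "count_min": 35, "count_max": null,
      "description": "35 or more protein-coding genes within the loss" },
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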