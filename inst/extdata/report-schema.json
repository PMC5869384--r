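{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "toxaudit evaluation report",
  "type": "object",
  "required": ["tier_counts", "venn", "fp_rates", "fp_rates_all_cds",
               "diversity", "pr", "correlations", "retention", "overlap",
               "clade_retention"],
  "properties": {
    "tier_counts": {
      "type": "object",
      "description": "per database tier: the four stage counts (unique contigs, unique CDS, unique CDS with signal peptide, unique full-length CDS)"
    },
    "venn": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["region", "count"],
        "properties": {
          "region": {"type": "string"},
          "count": {"type": "integer", "minimum": 0}
        }
      }
    },
    "fp_rates": {
      "type": "object",
      "description": "per-tier false-positive rate vs the venom proteome over unique signal-peptide-positive CDS ids; values in [0, 1]",
      "additionalProperties": {"type": "number", "minimum": 0, "maximum": 1}
    },
    "fp_rates_all_cds": {
      "type": "object",
      "description": "same rates over all annotated unique CDS ids (alternative denominator)",
      "additionalProperties": {"type": "number", "minimum": 0, "maximum": 1}
    },
    "diversity": {
      "type": "array",
      "description": "per tier and family: percentage of CDSs, delta vs the proteome profile in percentage points and as a fold ratio; percentages sum to 100 per tier"
    },
    "pr": {
      "type": "array",
      "description": "precision/recall/F1 vs ground truth per tier, unfiltered and expression-filtered (synthetic runs only)"
    },
    "correlations": {
      "type": "array",
      "description": "Spearman correlation between set membership and FPKM, per annotation set and tissue"
    },
    "retention": {
      "type": "object",
      "required": ["n_proteome", "n_retained", "fraction"],
      "properties": {
        "n_proteome": {"type": "integer", "minimum": 0},
        "n_retained": {"type": "integer", "minimum": 0},
        "fraction": {"type": ["number", "null"], "minimum": 0, "maximum": 1}
      }
    },
    "overlap": {
      "type": "array",
      "description": "intraspecific shared-cluster counts per identity threshold"
    },
    "clade_retention": {
      "type": "array",
      "description": "per family: leaves, evidence leaves, and leaves retained by the clade-evidence filter"
    }
  }
}
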