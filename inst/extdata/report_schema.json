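{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "dorfscan analysis report",
  "type": "object",
  "required": [
    "n_genes",
    "n_candidates",
    "fraction_mrnas_with_dorf",
    "n_translated_dorfs",
    "tier_table",
    "frame_table",
    "length_tests",
    "utr3_dorf_correlation",
    "te_overall"
  ],
  "properties": {
    "n_genes": {"type": "integer", "minimum": 1},
    "n_candidates": {"type": "integer", "minimum": 0},
    "fraction_mrnas_with_dorf": {"type": "number", "minimum": 0, "maximum": 1},
    "n_translated_dorfs": {"type": "integer", "minimum": 0},
    "tier_table": {"type": "array"},
    "frame_table": {"type": "array"},
    "length_tests": {"type": "object"},
    "utr3_dorf_correlation": {
      "type": "object",
      "required": ["pearson_r", "p_value"]
    },
    "te_overall": {
      "type": "object",
      "required": ["delta_median_log2", "p_value"]
    }
  }
}
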