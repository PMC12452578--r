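{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "sangermab workflow report",
  "type": "object",
  "required": ["tool", "version", "step", "params", "chains"],
  "properties": {
    "tool": {"type": "string", "const": "sangermab"},
    "version": {"type": "string"},
    "step": {"type": "integer", "enum": [1, 2]},
    "params": {
      "type": "object",
      "properties": {
        "identity_threshold": {"type": "number"},
        "tm_range": {"type": "array", "items": {"type": "number"}},
        "len_range": {"type": "array", "items": {"type": "number"}}
      }
    },
    "chains": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "properties": {
          "chain": {"type": "string"},
          "error": {"type": "string"},
          "n_reads": {"type": "integer"},
          "n_clusters": {"type": "integer"},
          "cluster_sizes": {"type": "array", "items": {"type": "integer"}},
          "flagged_read_pct": {"type": "number"},
          "annotation": {
            "type": "object",
            "properties": {
              "chain_type": {"type": "string"},
              "v_call": {"type": "string"},
              "d_call": {"type": "string"},
              "j_call": {"type": "string"},
              "total_identity_pct": {"type": "number"},
              "cdr3_nt": {"type": "string"},
              "cdr3_aa": {"type": "string"},
              "productive": {"type": "boolean"}
            }
          },
          "isotype": {
            "type": "object",
            "properties": {
              "subclass": {"type": "string"},
              "light_chain": {"type": "string"}
            }
          },
          "primer": {
            "type": "object",
            "properties": {
              "name": {"type": "string"},
              "sequence": {"type": "string"},
              "tm_celsius": {"type": "number"},
              "gc_fraction": {"type": "number"},
              "anchor": {"type": "string"}
            }
          }
        }
      }
    },
    "strain_comparison": {"type": "array"},
    "assembly": {"type": "object"},
    "fingerprint": {
      "type": "object",
      "properties": {
        "coverage_pct": {"type": "number"},
        "n_matches": {"type": "integer"},
        "cdr_assignments": {"type": "array"}
      }
    }
  }
}
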