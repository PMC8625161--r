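{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "gene2compounds",
  "description": "Reverse link index: one key per map gene-like symbol, each listing the compound ids that target it (possibly empty).",
  "type": "object",
  "required": ["header", "genes"],
  "properties": {
    "header": {
      "type": "object",
      "properties": {
        "map_checksum": { "type": "string" },
        "map_path": { "type": "string" },
        "sources": { "type": "array", "items": { "type": "string" } },
        "gene_like_only": { "type": "boolean" },
        "timestamp": { "type": "string" },
        "tool_version": { "type": "string" }
      }
    },
    "genes": {
      "type": "object",
      "additionalProperties": {
        "type": "array",
        "items": { "type": "string" },
        "uniqueItems": true
      }
    }
  }
}
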