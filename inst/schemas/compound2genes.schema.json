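{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "compound2genes",
  "description": "Forward link index: compound id to map-covered target gene symbols. Compounds with no map-covered target are omitted.",
  "type": "object",
  "required": ["header", "compounds"],
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
    "compounds": {
      "type": "object",
      "additionalProperties": {
        "type": "array",
        "items": { "type": "string" },
        "minItems": 1,
        "uniqueItems": true
      }
    }
  }
}
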