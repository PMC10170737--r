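{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Recommendation payload",
  "description": "JSON response body emitted for one recommendation request.",
  "type": "object",
  "required": ["status", "engine", "options", "diagnostics"],
  "properties": {
    "status": { "enum": ["ok", "no_recommendation"] },
    "engine": { "type": "string" },
    "reason": { "type": ["string", "null"] },
    "options": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["treatment", "score", "support", "rank", "contraindication"],
        "properties": {
          "treatment": { "type": "string" },
          "score": { "type": "number", "minimum": 0, "maximum": 1 },
          "support": { "type": "integer", "minimum": 0 },
          "rank": { "type": "integer", "minimum": 1 },
          "contraindication": { "enum": ["none", "relative", "absolute"] },
          "is_current_and_at_target": { "type": "boolean" }
        }
      }
    },
    "evidence": {
      "type": "array",
      "items": { "$ref": "contraindication-rule.schema.json#/items" }
    },
    "summaries": { "type": "object" },
    "diagnostics": {
      "type": "object",
      "required": ["engine", "scope", "mode", "neighborhood_size", "n_db", "fallback"],
      "properties": {
        "engine": { "type": "string" },
        "scope": { "enum": ["local", "global"] },
        "mode": { "enum": ["pop", "mean"] },
        "neighborhood_size": { "type": "integer", "minimum": 0 },
        "n_db": { "type": "integer", "minimum": 1 },
        "fallback": { "type": "boolean" }
      }
    }
  }
}
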