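{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Contraindication rule base",
  "description": "A rule base is a JSON array of rule records. Each record attaches one contraindication trigger to one antihypertensive treatment class.",
  "type": "array",
  "minItems": 1,
  "items": {
    "type": "object",
    "required": [
      "rule_id", "treatment", "trigger_type", "trigger_code", "level",
      "description", "source_type", "source_name", "source_date"
    ],
    "additionalProperties": false,
    "properties": {
      "rule_id": { "type": "string", "minLength": 1 },
      "treatment": { "type": "string", "minLength": 1 },
      "trigger_type": { "enum": ["comorbidity", "condition", "comedication"] },
      "trigger_code": { "type": "string", "minLength": 1 },
      "level": { "enum": ["absolute", "relative"] },
      "description": { "type": "string", "minLength": 1 },
      "source_type": { "enum": ["professional_information", "clinical_guideline"] },
      "source_name": { "type": "string", "minLength": 1 },
      "source_date": { "type": "string", "format": "date" }
    }
  }
}
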