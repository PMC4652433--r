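{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "famrisk pedigree",
  "description": "Schema version 1.0 for the famrisk pedigree JSON serialisation.",
  "type": "object",
  "required": ["schema_version", "relatives"],
  "properties": {
    "schema_version": {"const": "1.0"},
    "proband_note": {"type": "string"},
    "relatives": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["role"],
        "properties": {
          "role": {"enum": ["mother", "father",
            "maternal_grandmother", "maternal_grandfather",
            "paternal_grandmother", "paternal_grandfather",
            "maternal_aunt_uncle", "maternal_aunt_uncle_child",
            "paternal_aunt_uncle", "paternal_aunt_uncle_child",
            "sibling", "child"]},
          "member_index": {"type": "integer", "minimum": 0},
          "affected": {"type": "boolean"},
          "age_dx": {"type": "integer", "exclusiveMinimum": 0, "maximum": 120},
          "multiple_polyps": {"type": "boolean"},
          "other_cancers": {"type": "boolean"},
          "multiple_crc": {"type": "boolean"}
        }
      }
    }
  }
}
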