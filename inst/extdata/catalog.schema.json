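{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "catalog.schema.json",
  "title": "Experimental-action catalog",
  "description": "Schema of the YAML action catalog (expressed as JSON Schema over its data model). One entry per experimental action plus MIREOT records for imported external terms.",
  "type": "object",
  "required": ["version", "actions"],
  "properties": {
    "version": {"type": "string"},
    "actions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "label", "provenance"],
        "properties": {
          "id": {"type": "string", "pattern": "^EXACT2_[0-9]{6}$"},
          "label": {"type": "string"},
          "definition": {"type": "string"},
          "synonyms": {"type": "array", "items": {"type": "string"}},
          "provenance": {"enum": ["legacy", "added_v2", "imported_obi"]},
          "essential": {"$ref": "#/definitions/kinds"},
          "optional": {"$ref": "#/definitions/kinds"},
          "external_mapping": {"type": "string"}
        }
      }
    },
    "imported_terms": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["source_ontology", "term", "target_superclass"],
        "properties": {
          "source_ontology": {"type": "string", "minLength": 1},
          "term": {"type": "string", "minLength": 1},
          "target_superclass": {"type": "string", "minLength": 1},
          "label": {"type": "string"}
        }
      }
    }
  },
  "definitions": {
    "kinds": {
      "type": "array",
      "items": {
        "enum": [
          "biochemical_entity", "equipment", "temperature", "volume",
          "speed", "concentration", "period", "condition", "goal",
          "protocol_method", "time_point"
        ]
      }
    }
  }
}
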