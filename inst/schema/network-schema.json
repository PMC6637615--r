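{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "metregr network document",
  "type": "object",
  "required": ["entities", "reactions", "regulations", "transcription_units"],
  "properties": {
    "meta": {
      "type": "object",
      "properties": {"schema_version": {"type": "string"}}
    },
    "entities": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "kind"],
        "properties": {
          "id": {"type": "string"},
          "kind": {"enum": ["gene", "protein", "complex", "metabolite", "modified-form"]},
          "name": {"type": "string"},
          "ubiquitous": {"type": "boolean",
            "description": "compound excluded from substrate-role edges; when absent, a default name list (water, ATP, ...) is applied"},
          "base_entity": {"type": "string",
            "description": "required for (and only for) modified forms"},
          "gene": {"type": "string",
            "description": "for proteins: the encoding gene, used for logical-entity coalescing"},
          "components": {
            "type": "object",
            "additionalProperties": {"type": "number", "exclusiveMinimum": 0},
            "description": "complex composition: component entity id -> copy count; required for (and only for) complexes"
          }
        }
      }
    },
    "reactions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "reactants", "products"],
        "properties": {
          "id": {"type": "string"},
          "direction": {"enum": ["left-to-right", "right-to-left", "reversible"]},
          "reactants": {"type": "array", "items": {"type": "string"}, "minItems": 1},
          "products": {"type": "array", "items": {"type": "string"}, "minItems": 1},
          "enzymes": {"type": "array", "items": {"type": "string"}},
          "is_transport": {"type": "boolean"},
          "transported": {"type": "array", "items": {"type": "string"},
            "description": "subset of reactants + products"},
          "is_protein_binding": {"type": "boolean"}
        }
      }
    },
    "regulations": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "regulator", "regulatee", "mode"],
        "properties": {
          "id": {"type": "string"},
          "regulator": {"type": "string"},
          "regulatee": {"type": "string"},
          "mode": {"enum": ["transcriptional", "translational", "sigma-factor", "enzyme-modulation", "cofactor"]},
          "sign": {"enum": ["+", "-"],
            "description": "sigma-factor and cofactor records are always +"}
        }
      }
    },
    "transcription_units": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "genes"],
        "properties": {
          "id": {"type": "string"},
          "genes": {"type": "array", "items": {"type": "string"}, "minItems": 1}
        }
      }
    }
  }
}
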