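{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "elin causal statement file",
  "description": "A JSON array of text-mined causal statements. Each record links two grounded biological entities with a typed relationship, an evidence count and the early-life period the source literature covers. Validation is performed in code by parse_statements(); this document is the normative description of the dialect.",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["type", "subj", "obj", "period"],
    "properties": {
      "type": {
        "enum": ["Activation", "Inhibition", "IncreaseAmount",
                 "DecreaseAmount", "Complex", "Association"]
      },
      "subj": {"$ref": "#/$defs/entity"},
      "obj": {"$ref": "#/$defs/entity"},
      "evidence_count": {"type": "integer", "minimum": 1, "default": 1},
      "pmids": {"type": "array", "items": {"type": "string"}},
      "period": {"enum": ["EG", "MG", "LG", "BIRTH", "NEWBORN", "INFANT"]}
    }
  },
  "$defs": {
    "entity": {
      "type": "object",
      "required": ["name"],
      "properties": {
        "name": {"type": "string", "minLength": 1},
        "db_refs": {
          "type": "object",
          "description": "namespace -> identifier groundings; known namespaces: HGNC, FPLX, CHEBI, GO, GOSLIM, MESH, DOID, UMLS. A TEXT entry is ignored.",
          "additionalProperties": {"type": "string"}
        },
        "kind": {
          "enum": ["gene", "bioprocess"],
          "description": "optional kind hint for ungrounded entities"
        }
      }
    }
  }
}
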