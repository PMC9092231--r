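{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "crcsize analysis report",
  "type": "object",
  "required": ["tool", "input", "descriptives", "loglinear", "pairwise",
               "lcmcr", "config"],
  "properties": {
    "tool": {
      "type": "object",
      "required": ["package", "version"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"}
      }
    },
    "input": {
      "type": "object",
      "required": ["k", "eventNames", "n", "histories"],
      "properties": {
        "k": {"type": "integer", "minimum": 2},
        "eventNames": {"type": "array", "items": {"type": "string"}},
        "n": {"type": "integer", "minimum": 0},
        "histories": {
          "type": "object",
          "additionalProperties": {"type": "integer", "minimum": 0}
        }
      }
    },
    "descriptives": {
      "type": "object",
      "required": ["nj", "fi", "ui"]
    },
    "loglinear": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["spec", "model", "variant"],
        "properties": {
          "spec": {"type": "string"},
          "model": {"type": "string"},
          "variant": {"type": "string"},
          "Nhat": {"type": ["number", "null"]},
          "se": {"type": ["number", "null"]},
          "aic": {"type": ["number", "null"]},
          "bic": {"type": ["number", "null"]},
          "lowerBound": {"type": "boolean"}
        }
      }
    },
    "pairwise": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["pair", "nA", "nB", "m", "Nhat"]
      }
    },
    "bma": {
      "type": ["object", "null"],
      "required": ["mean", "median", "lower", "upper", "level", "delta",
                   "prior"]
    },
    "lcmcr": {
      "type": "object",
      "required": ["mean", "median", "lower", "upper", "level", "nDraws",
                   "ess", "config"]
    },
    "config": {
      "type": "object",
      "required": ["level", "seed"],
      "properties": {
        "level": {"type": "number"},
        "seed": {"type": "integer"}
      }
    }
  }
}
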