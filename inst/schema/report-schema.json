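{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "eccFinder pipeline run report",
  "type": "object",
  "required": ["schemaVersion", "seed", "parameters", "samples", "segments",
               "junctions", "topology"],
  "properties": {
    "schemaVersion": {"type": "string"},
    "seed": {"type": "integer"},
    "parameters": {
      "type": "object",
      "required": ["depth", "readLen", "window", "span", "threshold",
                   "minWindows", "minClip", "tol", "minSupport"],
      "properties": {
        "depth": {"type": "number"},
        "readLen": {"type": "integer"},
        "window": {"type": "integer"},
        "span": {"type": "number"},
        "threshold": {"type": "number"},
        "minWindows": {"type": "integer"},
        "minClip": {"type": "integer"},
        "tol": {"type": "integer"},
        "minSupport": {"type": "integer"}
      }
    },
    "samples": {"type": "object"},
    "segments": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["chrom", "start", "end", "direction", "fold"],
        "properties": {
          "chrom": {"type": "string"},
          "start": {"type": "integer"},
          "end": {"type": "integer"},
          "direction": {"type": "string"},
          "fold": {"type": "number"},
          "foldRounded": {"type": "number"},
          "meanSmoothed": {"type": "number"},
          "nWindows": {"type": "integer"}
        }
      }
    },
    "junctions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["chrom", "leftBp", "rightBp", "unitLength"],
        "properties": {
          "chrom": {"type": "string"},
          "leftBp": {"type": "integer"},
          "rightBp": {"type": "integer"},
          "unitLength": {"type": "integer"},
          "ambiguitySpan": {"type": "integer"},
          "supportLeft": {"type": "integer"},
          "supportRight": {"type": "integer"}
        }
      }
    },
    "topology": {
      "type": "object",
      "required": ["verdict", "p1", "has11kb", "hasHighMW"],
      "properties": {
        "verdict": {"type": "string"},
        "copiesPerAllele": {"type": "number"},
        "copiesFromIntensity": {"type": "number"},
        "agreement": {"type": "boolean"},
        "p1": {"type": "boolean"},
        "p2": {"type": "boolean"},
        "p3Short": {"type": "boolean"},
        "p3Long": {"type": "boolean"},
        "has11kb": {"type": "boolean"},
        "hasHighMW": {"type": "boolean"},
        "intensityRatio": {"type": "number"}
      }
    }
  }
}
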