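{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Skeleton stream (line-delimited JSON)",
  "description": "Line 1 is the header object; every following line is one frame object. All coordinates are meters: x lateral (+ toward the subject's right as seen by the sensor), y vertical up, z longitudinal along the walking direction.",
  "$defs": {
    "header": {
      "type": "object",
      "properties": {
        "fps": {"type": ["number", "null"], "exclusiveMinimum": 0},
        "subject_height": {"type": ["number", "null"], "exclusiveMinimum": 0},
        "source": {"type": "string"}
      },
      "required": ["fps", "subject_height", "source"]
    },
    "frame": {
      "type": "object",
      "properties": {
        "t": {"type": "number", "minimum": 0},
        "joints": {
          "type": "object",
          "minProperties": 20,
          "maxProperties": 20,
          "additionalProperties": {
            "type": "array", "items": {"type": "number"},
            "minItems": 3, "maxItems": 3
          }
        }
      },
      "required": ["t", "joints"]
    }
  }
}
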