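{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Threshold configuration (therapist-tunable)",
  "type": "object",
  "properties": {
    "strictness": {"type": "number", "exclusiveMinimum": 0},
    "overrides": {
      "type": "object",
      "additionalProperties": {"type": "number", "exclusiveMinimum": 0}
    },
    "included_parts": {
      "type": "array", "items": {"type": "string"}, "minItems": 1
    },
    "balance_epsilon": {"type": "number", "exclusiveMinimum": 0},
    "debounce_frames": {"type": "integer", "minimum": 1}
  },
  "required": ["strictness", "overrides", "included_parts",
               "balance_epsilon", "debounce_frames"]
}
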