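{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Session report",
  "type": "object",
  "properties": {
    "session_id": {"type": "string"},
    "patient_id": {"type": "string"},
    "attempts": {
      "type": "array",
      "items": {
        "type": "object",
        "properties": {
          "index": {"type": "integer", "minimum": 1},
          "complete": {"type": "boolean"},
          "success": {"type": "boolean"},
          "error_events": {
            "type": "array",
            "items": {
              "type": "object",
              "properties": {
                "id": {"type": "string"},
                "start_t": {"type": "number"},
                "end_t": {"type": "number"}
              },
              "required": ["id", "start_t", "end_t"]
            }
          },
          "duration": {"type": ["number", "null"]},
          "conclusions": {"type": "array", "items": {"type": "string"}}
        },
        "required": ["index", "complete", "success", "error_events",
                     "duration", "conclusions"]
      }
    },
    "totals": {"type": "object"},
    "config_snapshot": {"$ref": "threshold.schema.json"}
  },
  "required": ["session_id", "patient_id", "attempts", "totals",
               "config_snapshot"]
}
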