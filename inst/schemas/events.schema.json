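{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Feedback event log (line-delimited JSON, one event per line)",
  "type": "object",
  "properties": {
    "t": {"type": "number", "minimum": 0},
    "kind": {"enum": ["task_instruction", "balance_alert", "margin_touch",
                      "misaligned_bones", "corrective_arrow",
                      "congratulation", "conclusion"]},
    "severity": {"enum": ["informational", "intrusive"]},
    "payload": {"type": "object"}
  },
  "required": ["t", "kind", "severity", "payload"]
}
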