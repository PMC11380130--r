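{
  "name": "dsr_parent_ext",
  "n_items": 13,
  "response_range": [0, 4],
  "reverse_items": [],
  "subscales": {},
  "provenance": "Parenting-scenario extension of the revised Disgust Scale: 13 items scored like the first half of the DS-r (0-4), no subscales."
}
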