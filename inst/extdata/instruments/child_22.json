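{
  "name": "child_22",
  "n_items": 22,
  "response_range": [0, 3],
  "reverse_items": [],
  "subscales": {
    "core": [1, 2, 3, 4, 5, 6, 7, 8],
    "animal_reminder": [9, 10, 11, 12, 13, 14, 15],
    "contamination": [16, 17, 18, 19, 20, 21, 22]
  },
  "provenance": "SYNTHETIC default subscale map. The 22-item child disgust-sensitivity self-report (four response options, scored 0-3) does not publish its item keys alongside this package; replace this map with the source instrument's before substantive use."
}
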