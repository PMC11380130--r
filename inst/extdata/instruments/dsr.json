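{
  "name": "dsr",
  "n_items": 27,
  "response_range": [0, 4],
  "reverse_items": [],
  "subscales": {
    "core": [1, 2, 3, 4, 5, 15, 16, 17, 18, 19],
    "animal_reminder": [6, 7, 8, 9, 10, 20, 21, 22, 23],
    "contamination": [11, 12, 13, 14, 24, 25, 26, 27]
  },
  "provenance": "SYNTHETIC default subscale map for the revised Disgust Scale; reverse keying left empty because the published set is not reproduced here (27 items; agree/disagree statements 1-14, disgust-rating scenarios 15-27, scored 0-4). The published core/animal-reminder/contamination keys and reverse-scored items must be supplied from the source instrument before substantive use."
}
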