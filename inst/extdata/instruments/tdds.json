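{
  "name": "tdds",
  "n_items": 21,
  "response_range": [0, 6],
  "reverse_items": [],
  "subscales": {
    "moral": [1, 4, 7, 10, 13, 16, 19],
    "sexual": [2, 5, 8, 11, 14, 17, 20],
    "pathogen": [3, 6, 9, 12, 15, 18, 21]
  },
  "provenance": "Three-Domain Disgust Scale: 21 items on a 7-point scale (0-6), seven per subdomain, following the instrument's interleaved moral/sexual/pathogen administration order. Verify against the source instrument before substantive use."
}
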