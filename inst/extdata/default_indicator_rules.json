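[
  {
    "name": "reduced_consciousness",
    "field": "gcs",
    "operator": "lt",
    "threshold": 13
  },
  {
    "name": "hypotension",
    "field": "sbp",
    "operator": "lt",
    "threshold": 90
  },
  {
    "name": "intubated",
    "field": "intubation",
    "operator": "is_true"
  },
  {
    "name": "adrenaline_given",
    "field": "adrenaline",
    "operator": "is_true"
  }
]
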