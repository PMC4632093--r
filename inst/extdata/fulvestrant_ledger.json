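{
  "aliases": {
    "Myosin light chains": ["MYL2", "MYL9"]
  },
  "records": [
    {"gene": "BIK", "round": 1, "sources": "", "outcome": "validated", "corroboration": false},
    {"gene": "ERBB4", "round": 1, "sources": "", "outcome": "validated", "corroboration": false},
    {"gene": "DAPK3", "round": 1, "sources": "", "outcome": "validated", "corroboration": false},
    {"gene": "MAP2K2", "round": 1, "sources": "", "outcome": "validated", "corroboration": false},
    {"gene": "DAPK1", "round": 2, "sources": "DAPK3", "outcome": "validated", "corroboration": false},
    {"gene": "DAPK2", "round": 2, "sources": "DAPK3", "outcome": "validated", "corroboration": false},
    {"gene": "ROCK1", "round": 2, "sources": "DAPK3", "outcome": "validated", "corroboration": false},
    {"gene": "MYL2", "round": 2, "sources": "DAPK3", "outcome": "untestable_toxic", "corroboration": false},
    {"gene": "MYL9", "round": 2, "sources": "DAPK3", "outcome": "untestable_toxic", "corroboration": false},
    {"gene": "DAXX", "round": 2, "sources": "DAPK3", "outcome": "negative", "corroboration": false},
    {"gene": "NR3C1", "round": 2, "sources": "DAPK3", "outcome": "negative", "corroboration": false},
    {"gene": "ATF4", "round": 2, "sources": "DAPK3", "outcome": "negative", "corroboration": false},
    {"gene": "PAWR", "round": 2, "sources": "DAPK3", "outcome": "negative", "corroboration": false},
    {"gene": "PRKCZ", "round": 2, "sources": "DAPK3", "outcome": "negative", "corroboration": false},
    {"gene": "GRB14", "round": 2, "sources": "DAPK3", "outcome": "negative", "corroboration": false},
    {"gene": "F2RL3", "round": 2, "sources": "DAPK3", "outcome": "negative", "corroboration": false},
    {"gene": "PPP1R12A", "round": 2, "sources": "DAPK3", "outcome": "negative", "corroboration": false},
    {"gene": "TP53", "round": 2, "sources": "BIK", "outcome": "validated", "corroboration": false},
    {"gene": "MYLK3", "round": 3, "sources": "MYL2;MYL9", "outcome": "validated", "corroboration": false},
    {"gene": "MAPK9", "round": 3, "sources": "TP53", "outcome": "validated", "corroboration": false},
    {"gene": "CAMK1D", "round": 3, "sources": "DAPK1;DAPK2", "outcome": "validated", "corroboration": false},
    {"gene": "CAMK4", "round": 3, "sources": "DAPK1;DAPK2", "outcome": "validated", "corroboration": false},
    {"gene": "CALM1", "round": 4, "sources": "CAMK1D;CAMK4;DAPK1;DAPK2", "outcome": "validated", "corroboration": false},
    {"gene": "MAP2K7", "round": 4, "sources": "MAP2K2;MAPK9", "outcome": "validated", "corroboration": false},
    {"gene": "STAT3", "round": 4, "sources": "ERBB4;ROCK1", "outcome": "untestable_toxic", "corroboration": false},
    {"gene": "PAG1", "round": 4, "sources": "STAT3;ERBB4", "outcome": "validated", "corroboration": false},
    {"gene": "STAT5A", "round": 4, "sources": "ERBB4", "outcome": "untestable_failed", "corroboration": true},
    {"gene": "CSK", "round": 5, "sources": "PAG1", "outcome": "validated", "corroboration": false}
  ]
}
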