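[
  {"a": "Aves",          "b": "Crocodylia",     "age": 244.8},
  {"a": "Aves",          "b": "Testudines",     "age": 261.4},
  {"a": "Aves",          "b": "Lepidosauria",   "age": 279.9},
  {"a": "Aves",          "b": "Mammalia",       "age": 318.9},
  {"a": "Aves",          "b": "Amphibia",       "age": 351.7},
  {"a": "Aves",          "b": "Actinopterygii", "age": 429.0},
  {"a": "Aves",          "b": "Chondrichthyes", "age": 462.4},
  {"a": "Aves",          "b": "Agnatha",        "age": 563.4}
]
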