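{
  "description": "Hand-built fixture network; relation provenance is documented in toy_network()'s manifest attribute.",
  "counts": {
    "entities": 23,
    "reactions": 5,
    "regulations": 5,
    "transcription_units": 1
  }
}
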