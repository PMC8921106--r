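species: human
events:
  time: []
  route: []
  dose: []
rates:
  start: 0.0
  stop: 24000.0
  rate: 0.007
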