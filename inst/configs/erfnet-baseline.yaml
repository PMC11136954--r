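preset: erfnet-baseline
train:
  lr: 0.0025
  epochs: 400
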