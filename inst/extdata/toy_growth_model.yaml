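group: subject
outcomes:
  - name: y1
    fixed: [V1, sex]
    random: [age]
  - name: y2
    fixed: [V2, sex]
    random: [age]
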