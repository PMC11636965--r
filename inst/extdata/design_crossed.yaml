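# Two-stage SMART: two consolidation-type options crossed with two
# maintenance-type options for every subject completing the first stage.
label: consolidation x maintenance
stages:
  - options: ["0", "1"]
    strata:
      - key: {}
        feasible: ["0", "1"]
        probs: [0.5, 0.5]
  - options: ["0", "1"]
    strata:
      - key: {}
        feasible: ["0", "1"]
        probs: [0.5, 0.5]
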