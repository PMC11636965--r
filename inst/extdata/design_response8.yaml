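# Two-stage SMART: two initial options; subjects event-free at decision 2
# are classified as responders/nonresponders and re-randomized within
# feasibility strata determined by initial treatment and response status.
label: response-stratified, 8 embedded regimes
stages:
  - options: ["0", "1"]
    strata:
      - key: {}
        feasible: ["0", "1"]
        probs: [0.5, 0.5]
  - options: ["2", "3", "4", "5"]
    strata:
      - key: {a1: "1", x2_resp: 1}
        feasible: ["2", "5"]
        probs: [0.5, 0.5]
      - key: {a1: "1", x2_resp: 0}
        feasible: ["3", "5"]
        probs: [0.5, 0.5]
      - key: {a1: "0", x2_resp: 1}
        feasible: ["2", "4"]
        probs: [0.5, 0.5]
      - key: {a1: "0", x2_resp: 0}
        feasible: ["3", "4"]
        probs: [0.5, 0.5]
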