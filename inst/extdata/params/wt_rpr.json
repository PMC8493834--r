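{
  "p1": 6.67e-03, "p2": 7.52e-02, "p3": 2.71e-04, "p4": 2.44e-02,
  "p5": 1.72e-01, "p6": 2.18e-02, "p7": 7.12e-02, "p8": 3.13e-02,
  "p9": 6.21e+02, "p10": 7.81e-03, "p11": 2.10e+02, "p12": 5.03e-04,
  "label": "WT+RPR"
}
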