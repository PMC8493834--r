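{
  "p1": 6.49e-03, "p2": 6.97e-02, "p3": 7.35e-03, "p4": 1.49e-07,
  "p5": 2.44e-01, "p6": 2.18e-02, "p7": 8.10e-02, "p8": 1.98e-02,
  "p9": 2.04e-01, "p10": 6.74e-02, "p11": 6.73e-03, "p12": 2.94e-02,
  "label": "R56Q"
}
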