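{
  "p1": 7.66e-03, "p2": 6.99e-02, "p3": 1.44e-03, "p4": 1.43e-02,
  "p5": 1.48e-01, "p6": 2.76e-02, "p7": 8.74e-02, "p8": 3.26e-02,
  "p9": 1.19e-01, "p10": 5.30e-03, "p11": 8.60e-02, "p12": 7.98e-03,
  "label": "R56Q+RPR"
}
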