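{
  "p1": 8.53e-03, "p2": 8.32e-02, "p3": 1.26e-02, "p4": 1.04e-07,
  "p5": 2.70e-01, "p6": 1.58e-02, "p7": 7.67e-02, "p8": 2.25e-02,
  "p9": 1.49e-01, "p10": 2.43e-02, "p11": 5.58e-04, "p12": 4.07e-02,
  "label": "WT"
}
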