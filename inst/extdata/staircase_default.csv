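duration_ms,voltage_mV
250,-80
250,-120
200,-80
1000,40
500,-120
1000,-80
500,-40
500,-60
500,-20
500,-40
500,0
500,-20
500,20
500,0
500,40
500,20
500,60
500,0
250,-40
250,-60
500,-20
500,-80
500,-40
250,-100
500,-60
250,-120
500,40
500,-70
500,-110
500,-80
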