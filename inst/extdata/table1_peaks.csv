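rt_min,mz,intensity,id
22.70,1040.7147,1.0,P1
23.39,1054.7286,1.0,P2
23.67,994.6701,1.0,P3
24.50,1008.6832,1.0,P4
25.85,1022.6963,1.0,P5
26.56,1036.7073,1.0,P6
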