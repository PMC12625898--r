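mz,intensity
1235.71,100
1478.74,74
1580.86,62
2115.19,48
2869.56,33
2957.68,29
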