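stopw01
stopw02
stopw03
stopw04
stopw05
stopw06
stopw07
stopw08
stopw09
stopw10
stopw11
stopw12
stopw13
stopw14
stopw15
stopw16
stopw17
stopw18
stopw19
stopw20
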