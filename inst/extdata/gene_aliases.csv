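alias,canonical
carl3,calr3
r1f,rlf
rio1,riok1
igbo-v7183,igh-v7183
atpla2,atp1a2
parkar1b,prkar1b
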