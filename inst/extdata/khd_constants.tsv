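# Kim-Hummer model D scaling constants for the Miyazawa-Jernigan mapping
# epsilon_ij = |alpha * (e_MJ,ij - e0)|, attractive tail when
# alpha * (e_MJ,ij - e0) <= 0.
key	value
alpha	0.228
e0	-1.8
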