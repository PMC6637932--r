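region	n_total	n_amplified	length_min	length_max
ITS	34	34	605	615
IGS	34	34	415	440
nLSU	34	33	934	939
mtSSU	34	32	662	740
tef1	34	23	861	920
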