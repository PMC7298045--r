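chain	position	residue	frequency	n_obs
heavy	14	R	0.0015	0
heavy	14	P	0.9503	0
heavy	20	P	0.0009	0
heavy	20	L	0.7302	0
heavy	81	H	0.016	0
heavy	81	Q	0.5758	0
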