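>IGHV3-23-like-scaffold_heavy
EVQLLESGGGLVQPGGSLRLSCAASGFTFSSYAMSWVRQAPGKGLEWVSAISGSGGTYYA
DSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYYCAK
>IGKV1-17-like-scaffold_kappa
DIQMTQSPSSLSASVGDRVTITCRASQGISNYLAWYQQKPGKAPKLLIYAASTLQSGVPS
RFSGSGSGTDFTLTISSLQPEDVATYYCLQHNSYPLTFGGGTKVEIK
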