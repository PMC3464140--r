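assay_name	name	role	sequence	ref_start	ref_end
narrow_v34_synthetic	narrow_F	forward_primer	CCTACGGGAGGCAGCA	341	356
narrow_v34_synthetic	narrow_R	reverse_primer	GGACTACCAGGGTATCTAATC	786	806
narrow_v34_synthetic	narrow_P	probe	CAGCAGCCGCGGTA	519	532
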