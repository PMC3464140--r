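assay_name	name	role	sequence	ref_start	ref_end
panbact_v34	panbact_F	forward_primer	CCTACGGGDGGCWGCA	341	356
panbact_v34	panbact_R	reverse_primer	GGACTACHVGGGTMTCTAATC	786	806
panbact_v34	panbact_P	probe	CAGCAGCCGCGGTA	519	532
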