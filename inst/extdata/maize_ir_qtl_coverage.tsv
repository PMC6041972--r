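tissue_class	qtl_coverage_cM
kernel	2702.35
leaf	4024.24
stem	5558.27
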