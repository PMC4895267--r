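group	region_class	combine	n_candidate	n_associated	reported_pct
ESC	enhancer	union	4056578	51666	1.27
ESC	promoter	union	1401636	11942	0.85
iPSC	enhancer	union	4056578	20553	0.51
iPSC	promoter	union	1401636	3697	0.26
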