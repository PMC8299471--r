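TMD_up	example dormancy program	STAT1	CXCL9	CXCL10	GZMB	PRF1	PLG	PLAUR	THBS1
TMD_down	example dormancy program	VEGFA	HIF1A
APOBEC	example mean-expression program	APOBEC3A	APOBEC3B	APOBEC3G	AICDA
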