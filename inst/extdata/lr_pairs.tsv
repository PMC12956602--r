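ligand	receptor	source
CSF3	CSF3R	curated
SAA1	FPR1	curated
CCL19	CCR7	curated
CXCL12	CXCR4	curated
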