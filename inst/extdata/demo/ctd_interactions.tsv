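# synthetic demonstration rows in the CTD-style dialect (not CTD data)
ChemicalName	CasRN	GeneSymbol	InteractionActions
Curcumin	458-37-7	CFTR	affects^folding
Curcumin	458-37-7	HSP90AA1	decreases^activity
Curcumin	458-37-7	KEAP1	decreases^binding
Genistein	446-72-0	CFTR	increases^activity
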