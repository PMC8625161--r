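# synthetic demonstration rows in the ChEMBL-style dialect (not ChEMBL data)
compound_key	gene_symbol	target_name
PURKAOJPTOLRMP-UHFFFAOYSA-N	CFTR	Cystic fibrosis transmembrane conductance regulator
VFLDPWHFBUODDF-FCXRPNKRSA-N	HSP90AA1	Heat shock protein HSP 90-alpha
5280961	ESR1	Estrogen receptor alpha
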