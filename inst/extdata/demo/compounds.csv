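compound_id,inchikey,smiles,cas_number,pubchem_cid,names
CAND001,VFLDPWHFBUODDF-FCXRPNKRSA-N,COC1=CC(C=CC(=O)CC(=O)C=CC2=CC(OC)=C(O)C=C2)=CC=C1O,458-37-7,969516,Curcumin|Diferuloylmethane|Turmeric yellow
CAND002,PURKAOJPTOLRMP-UHFFFAOYSA-N,CC(C)(C)C1=CC(=C(C=C1NC(=O)C2=CNC3=CC=CC=C3C2=O)O)C(C)(C)C,873054-44-5,16220172,Ivacaftor|VX-770|Kalydeco
CAND003,TZBJGXHYKVUXJN-UHFFFAOYSA-N,C1=CC(=CC=C1C2=COC3=CC(=CC(=C3C2=O)O)O)O,446-72-0,5280961,Genistein|Genisteol
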