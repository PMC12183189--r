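pathway	node_a	node_b
amino_acid_osmolytes	glutamate	ornithine
amino_acid_osmolytes	ornithine	citrulline
amino_acid_osmolytes	citrulline	arginine
amino_acid_osmolytes	glutamate	proline
amino_acid_osmolytes	glutamate	GABA
amino_acid_osmolytes	saccharopine	proline
sugars_polyols	sucrose	glucose
sugars_polyols	sucrose	fructose
sugars_polyols	sucrose	raffinose
sugars_polyols	myo-inositol	raffinose
sugars_polyols	glucose	myo-inositol
sulfur_redox	cysteine	taurine
sulfur_redox	cysteine	methionine
sulfur_redox	cysteine	glutathione_reduced_GSH
sulfur_redox	glutathione_reduced_GSH	glutathione_oxidized_GSSG
aromatic_aa	phenylalanine	tyrosine
aromatic_aa	serine	tryptophan
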