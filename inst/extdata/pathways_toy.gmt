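amino_acid_osmolytes	Proline, arginine and glutamate-family osmolytes	proline	glutamate	ornithine	arginine	citrulline	GABA	saccharopine
sugars_polyols	Sugars and sugar alcohols	sucrose	glucose	fructose	raffinose	myo-inositol
sulfur_redox	Sulfur amino acids, taurine and glutathione	cysteine	methionine	taurine	glutathione_reduced_GSH	glutathione_oxidized_GSSG
aromatic_aa	Aromatic and hydroxy amino acids	phenylalanine	tyrosine	tryptophan	serine
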