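metabolite	step	role	transcript
proline	glutamate 5-kinase	synthesis	g5k_1
proline	glutamate-5-semialdehyde dehydrogenase	synthesis	g5sd_1
proline	proline dehydrogenase	degradation	prodh_1
proline	pipecolate oxidase (pipecolate shunt)	competing	pox_1
saccharopine	lysine-ketoglutarate reductase/saccharopine dehydrogenase	synthesis	lkr_sdh1
taurine	cysteate decarboxylase	synthesis	tau_syn1
taurine	5-glutamyl-taurine transferase	degradation	tau_glu1
glutamate	glutamate synthase	degradation	gogat_1
glutamate	glutamate decarboxylase A	degradation	gad_a1
GABA	glutamate decarboxylase A	synthesis	gad_a1
fructose	invertase	synthesis	inv_1
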