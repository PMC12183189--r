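transcript	region	log2fc
g5k_1	R1	2.6
g5k_1	R2	2.4
g5k_1	R3	2.2
g5sd_1	R1	2.1
g5sd_1	R2	2.3
g5sd_1	R3	2.0
prodh_1	R1	-2.2
prodh_1	R2	-2.4
prodh_1	R3	-2.1
pox_1	R1	-2.5
pox_1	R2	-2.8
pox_1	R3	-2.6
lkr_sdh1	R1	0.2
lkr_sdh1	R2	0.1
lkr_sdh1	R3	0.3
tau_syn1	R1	2.2
tau_syn1	R2	2.0
tau_syn1	R3	0.4
tau_glu1	R1	1.6
tau_glu1	R2	1.4
tau_glu1	R3	0.2
gogat_1	R1	-1.3
gogat_1	R2	-1.5
gogat_1	R3	-1.4
gad_a1	R1	1.7
gad_a1	R2	1.9
gad_a1	R3	1.8
inv_1	R1	0.3
inv_1	R2	0.2
inv_1	R3	0.4
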