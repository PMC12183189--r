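region	up_tier2	down_tier2	up_tier1	down_tier1	n_transcripts
R1	63	41	104	91	45764
R2	168	382	384	845	45764
R3	182	183	396	493	45764
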