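name	mono_mass	residues	provenance
carbamylation	43.0058	N-term	urea-derived chemical artifact
carbamidomethyl	57.0215	C	iodoacetamide alkylation (common fixed mod)
oxidation	15.9949	M	common variable modification
dioxidation	31.9898	M,C	double oxidation
sulfinic_acid	31.9898	C	cysteine oxidation to sulfinic acid
cysteic_acid	47.9847	C	cysteine oxidation to cysteic acid
phospho	79.9663	S,T,Y	phosphorylation
acetyl	42.0106	K,N-term	acetylation
methyl	14.0157	K,R	methylation
deamidation	0.9840	N,Q	deamidation
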