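# Final consensus odorant panel: 4 distinctive vs 7 non-distinctive odors.
# Structures curated from public chemical-structure databases (the study
# identifies the compounds by name and CAS number only).
# Format: name<TAB>smiles<TAB>label
cis-3-hexenol	CC/C=C\CCO	distinctive
methyl salicylate	COC(=O)c1ccccc1O	distinctive
1-butanol	CCCCO	distinctive
cineole	CC1(C2CCC(O1)(CC2)C)C	distinctive
benzyl acetate	CC(=O)OCc1ccccc1	nondistinctive
heptanal	CCCCCCC=O	nondistinctive
4-ethyloctanoic acid	CCCCC(CC)CCC(=O)O	nondistinctive
methional	CSCCC=O	nondistinctive
isobutyric acid	CC(C)C(=O)O	nondistinctive
4-decanolide	CCCCCCC1CCC(=O)O1	nondistinctive
p-cresol	Cc1ccc(O)cc1	nondistinctive
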