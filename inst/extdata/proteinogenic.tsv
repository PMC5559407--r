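id	name	class	smiles
ala	alanine	proteinogenic_aa	[NH2:2]C(C)[C:1](=O)O
arg	arginine	proteinogenic_aa	[NH2:2]C(CCCNC(=N)N)[C:1](=O)O
asn	asparagine	proteinogenic_aa	[NH2:2]C(CC(N)=O)[C:1](=O)O
asp	aspartate	proteinogenic_aa	[NH2:2]C(CC(O)=O)[C:1](=O)O
cys	cysteine	proteinogenic_aa	[NH2:2]C(CS)[C:1](=O)O
gln	glutamine	proteinogenic_aa	[NH2:2]C(CCC(N)=O)[C:1](=O)O
glu	glutamate	proteinogenic_aa	[NH2:2]C(CCC(O)=O)[C:1](=O)O
gly	glycine	proteinogenic_aa	[NH2:2]C[C:1](=O)O
his	histidine	proteinogenic_aa	[NH2:2]C(CC1=CNC=N1)[C:1](=O)O
ile	isoleucine	proteinogenic_aa	[NH2:2]C(C(C)CC)[C:1](=O)O
leu	leucine	proteinogenic_aa	[NH2:2]C(CC(C)C)[C:1](=O)O
lys	lysine	proteinogenic_aa	[NH2:2]C(CCCCN)[C:1](=O)O
met	methionine	proteinogenic_aa	[NH2:2]C(CCSC)[C:1](=O)O
phe	phenylalanine	proteinogenic_aa	[NH2:2]C(CC1=CC=CC=C1)[C:1](=O)O
pro	proline	proteinogenic_aa	[NH:2]1CCCC1[C:1](=O)O
ser	serine	proteinogenic_aa	[NH2:2]C(CO)[C:1](=O)O
thr	threonine	proteinogenic_aa	[NH2:2]C(C(C)O)[C:1](=O)O
trp	tryptophan	proteinogenic_aa	[NH2:2]C(CC1=CNC2=CC=CC=C12)[C:1](=O)O
tyr	tyrosine	proteinogenic_aa	[NH2:2]C(CC1=CC=C(O)C=C1)[C:1](=O)O
val	valine	proteinogenic_aa	[NH2:2]C(C(C)C)[C:1](=O)O
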