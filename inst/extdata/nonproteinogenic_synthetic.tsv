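id	name	class	category	core32	smiles
bht	beta-hydroxytyrosine	nonproteinogenic_aa	beta_hydroxy	TRUE	[NH2:2]C(C(O)C1=CC=C(O)C=C1)[C:1](=O)O
bhp	beta-hydroxyphenylalanine	nonproteinogenic_aa	beta_hydroxy	TRUE	[NH2:2]C(C(O)C1=CC=CC=C1)[C:1](=O)O
bhd	beta-hydroxyaspartate	nonproteinogenic_aa	beta_hydroxy	TRUE	[NH2:2]C(C(O)C(O)=O)[C:1](=O)O
bhn	beta-hydroxyasparagine	nonproteinogenic_aa	beta_hydroxy	TRUE	[NH2:2]C(C(O)C(N)=O)[C:1](=O)O
bhl	beta-hydroxyleucine	nonproteinogenic_aa	beta_hydroxy	TRUE	[NH2:2]C(C(O)C(C)C)[C:1](=O)O
bhv	beta-hydroxyvaline	nonproteinogenic_aa	beta_hydroxy	FALSE	[NH2:2]C(C(O)(C)C)[C:1](=O)O
bmp	beta-methylphenylalanine	nonproteinogenic_aa	beta_methyl	TRUE	[NH2:2]C(C(C)C1=CC=CC=C1)[C:1](=O)O
bmt	beta-methyltyrosine	nonproteinogenic_aa	beta_methyl	TRUE	[NH2:2]C(C(C)C1=CC=C(O)C=C1)[C:1](=O)O
bmw	beta-methyltryptophan	nonproteinogenic_aa	beta_methyl	TRUE	[NH2:2]C(C(C)C1=CNC2=CC=CC=C12)[C:1](=O)O
bmd	beta-methylaspartate	nonproteinogenic_aa	beta_methyl	FALSE	[NH2:2]C(C(C)C(O)=O)[C:1](=O)O
lac	lactate	nonproteinogenic_aa	alpha_keto	TRUE	[OH:2]C(C)[C:1](=O)O
hiv	2-hydroxyisovalerate	nonproteinogenic_aa	alpha_keto	TRUE	[OH:2]C(C(C)C)[C:1](=O)O
hic	2-hydroxyisocaproate	nonproteinogenic_aa	alpha_keto	TRUE	[OH:2]C(CC(C)C)[C:1](=O)O
pla	phenyllactate	nonproteinogenic_aa	alpha_keto	TRUE	[OH:2]C(CC1=CC=CC=C1)[C:1](=O)O
hbu	2-hydroxybutyrate	nonproteinogenic_aa	alpha_keto	FALSE	[OH:2]C(CC)[C:1](=O)O
bala	beta-alanine	nonproteinogenic_aa	beta_amino	TRUE	[NH2:2]CC[C:1](=O)O
baib	3-aminoisobutyrate	nonproteinogenic_aa	beta_amino	FALSE	[NH2:2]CC(C)[C:1](=O)O
bphe	beta-phenylalanine	nonproteinogenic_aa	beta_amino	TRUE	[NH2:2]C(C1=CC=CC=C1)C[C:1](=O)O
btyr	beta-tyrosine	nonproteinogenic_aa	beta_amino	FALSE	[NH2:2]C(C1=CC=C(O)C=C1)C[C:1](=O)O
blys	beta-lysine	nonproteinogenic_aa	beta_amino	FALSE	[NH2:2]C(CCCN)C[C:1](=O)O
orn	ornithine	nonproteinogenic_aa	modified	TRUE	[NH2:2]C(CCCN)[C:1](=O)O
cit	citrulline	nonproteinogenic_aa	modified	TRUE	[NH2:2]C(CCCNC(N)=O)[C:1](=O)O
dab	2,4-diaminobutyrate	nonproteinogenic_aa	modified	TRUE	[NH2:2]C(CCN)[C:1](=O)O
dap	2,3-diaminopropionate	nonproteinogenic_aa	modified	TRUE	[NH2:2]C(CN)[C:1](=O)O
hyp	4-hydroxyproline	nonproteinogenic_aa	modified	TRUE	[NH:2]1CC(O)CC1[C:1](=O)O
kyn	kynurenine	nonproteinogenic_aa	modified	TRUE	[NH2:2]C(CC(=O)C1=CC=CC=C1N)[C:1](=O)O
hse	homoserine	nonproteinogenic_aa	modified	TRUE	[NH2:2]C(CCO)[C:1](=O)O
hty	homotyrosine	nonproteinogenic_aa	modified	TRUE	[NH2:2]C(CCC1=CC=C(O)C=C1)[C:1](=O)O
hph	homophenylalanine	nonproteinogenic_aa	modified	FALSE	[NH2:2]C(CCC1=CC=CC=C1)[C:1](=O)O
nva	norvaline	nonproteinogenic_aa	modified	TRUE	[NH2:2]C(CCC)[C:1](=O)O
nle	norleucine	nonproteinogenic_aa	modified	FALSE	[NH2:2]C(CCCC)[C:1](=O)O
abu	2-aminobutyrate	nonproteinogenic_aa	modified	TRUE	[NH2:2]C(CC)[C:1](=O)O
aib	2-aminoisobutyrate	nonproteinogenic_aa	modified	TRUE	[NH2:2]C(C)(C)[C:1](=O)O
dha	dehydroalanine	nonproteinogenic_aa	modified	TRUE	[NH2:2]C(=C)[C:1](=O)O
dhbu	dehydrobutyrine	nonproteinogenic_aa	modified	TRUE	[NH2:2]C(=CC)[C:1](=O)O
phg	phenylglycine	nonproteinogenic_aa	modified	TRUE	[NH2:2]C(C1=CC=CC=C1)[C:1](=O)O
hpg	4-hydroxyphenylglycine	nonproteinogenic_aa	modified	TRUE	[NH2:2]C(C1=CC=C(O)C=C1)[C:1](=O)O
dpg	3,5-dihydroxyphenylglycine	nonproteinogenic_aa	modified	TRUE	[NH2:2]C(C1=CC(O)=CC(O)=C1)[C:1](=O)O
pip	pipecolate	nonproteinogenic_aa	modified	TRUE	[NH:2]1CCCCC1[C:1](=O)O
mpr	4-methylproline	nonproteinogenic_aa	modified	FALSE	[NH:2]1CC(C)CC1[C:1](=O)O
mgl	3-methylglutamate	nonproteinogenic_aa	modified	FALSE	[NH2:2]C(C(C)CC(O)=O)[C:1](=O)O
aad	2-aminoadipate	nonproteinogenic_aa	modified	FALSE	[NH2:2]C(CCCC(O)=O)[C:1](=O)O
htrp	5-hydroxytryptophan	nonproteinogenic_aa	modified	FALSE	[NH2:2]C(CC1=CNC2=CC=C(O)C=C12)[C:1](=O)O
clt	4-chlorothreonine	nonproteinogenic_aa	modified	FALSE	[NH2:2]C(C(O)CCl)[C:1](=O)O
hor	N5-hydroxyornithine	nonproteinogenic_aa	modified	TRUE	[NH2:2]C(CCCNO)[C:1](=O)O
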