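id	name	class	subclass	smiles
but	butyrate	starter	fatty	CCC[C:1](=O)O
hexa	hexanoate	starter	fatty	CCCCC[C:1](=O)O
octa	octanoate	starter	fatty	CCCCCCC[C:1](=O)O
mbu	3-methylbutyrate	starter	fatty	CC(C)C[C:1](=O)O
bza	benzoate	starter	aromatic	O[C:1](=O)C1=CC=CC=C1
sal	salicylate	starter	aromatic	O[C:1](=O)C1=CC=CC=C1O
phb	4-hydroxybenzoate	starter	aromatic	O[C:1](=O)C1=CC=C(O)C=C1
dhb23	2,3-dihydroxybenzoate	starter	aromatic	O[C:1](=O)C1=CC=CC(O)=C1O
dhb35	3,5-dihydroxybenzoate	starter	aromatic	O[C:1](=O)C1=CC(O)=CC(O)=C1
ant	anthranilate	starter	aromatic	O[C:1](=O)C1=CC=CC=C1N
pab	4-aminobenzoate	starter	aromatic	O[C:1](=O)C1=CC=C(N)C=C1
nic	nicotinate	starter	aromatic	O[C:1](=O)C1=CC=CN=C1
paa	phenylacetate	starter	aromatic	O[C:1](=O)CC1=CC=CC=C1
cin	cinnamate	starter	aromatic	O[C:1](=O)C=CC1=CC=CC=C1
cou	4-coumarate	starter	aromatic	O[C:1](=O)C=CC1=CC=C(O)C=C1
caf	caffeate	starter	aromatic	O[C:1](=O)C=CC1=CC=C(O)C(O)=C1
pca	protocatechuate	starter	aromatic	O[C:1](=O)C1=CC=C(O)C(O)=C1
chc	cyclohexanecarboxylate	starter	alicyclic	O[C:1](=O)C1CCCCC1
che	cyclohex-1-ene-carboxylate	starter	alicyclic	O[C:1](=O)C1=CCCCC1
cpc	cyclopentanecarboxylate	starter	alicyclic	O[C:1](=O)C1CCCC1
ace	acetate	starter	small	C[C:1](=O)O
prp	propionate	starter	small	CC[C:1](=O)O
ibu	isobutyrate	starter	small	CC(C)[C:1](=O)O
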