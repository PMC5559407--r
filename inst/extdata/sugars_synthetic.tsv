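id	name	deoxy	smiles
s_hex_ohohoh	hexose-2OH-3OH-4OH	FALSE	[CH:1]1(O)C(O)C(O)C(O)C(CO)O1
s_dox_ohohoh	6-deoxy-2OH-3OH-4OH	TRUE	[CH:1]1(O)C(O)C(O)C(O)C(C)O1
s_hex_hohoh	hexose-2deoxy-3OH-4OH	TRUE	[CH:1]1(O)CC(O)C(O)C(CO)O1
s_hex_nmohoh	hexose-2NMe2-3OH-4OH	FALSE	[CH:1]1(O)C(N(C)C)C(O)C(O)C(CO)O1
s_hex_nohoh	hexose-2NH2-3OH-4OH	FALSE	[CH:1]1(O)C(N)C(O)C(O)C(CO)O1
s_hex_ohhoh	hexose-2OH-3deoxy-4OH	TRUE	[CH:1]1(O)C(O)CC(O)C(CO)O1
s_hex_ohnmoh	hexose-2OH-3NMe2-4OH	FALSE	[CH:1]1(O)C(O)C(N(C)C)C(O)C(CO)O1
s_hex_ohnoh	hexose-2OH-3NH2-4OH	FALSE	[CH:1]1(O)C(O)C(N)C(O)C(CO)O1
s_hex_ohohh	hexose-2OH-3OH-4deoxy	TRUE	[CH:1]1(O)C(O)C(O)CC(CO)O1
s_hex_ohohn	hexose-2OH-3OH-4NH2	FALSE	[CH:1]1(O)C(O)C(O)C(N)C(CO)O1
s_hex_ohohnm	hexose-2OH-3OH-4NMe2	FALSE	[CH:1]1(O)C(O)C(O)C(N(C)C)C(CO)O1
s_hex_ohohom	hexose-2OH-3OH-4OMe	FALSE	[CH:1]1(O)C(O)C(O)C(OC)C(CO)O1
s_hex_ohomoh	hexose-2OH-3OMe-4OH	FALSE	[CH:1]1(O)C(O)C(OC)C(O)C(CO)O1
s_hex_omohoh	hexose-2OMe-3OH-4OH	FALSE	[CH:1]1(O)C(OC)C(O)C(O)C(CO)O1
s_dox_hohoh	6-deoxy-2deoxy-3OH-4OH	TRUE	[CH:1]1(O)CC(O)C(O)C(C)O1
s_dox_nmohoh	6-deoxy-2NMe2-3OH-4OH	TRUE	[CH:1]1(O)C(N(C)C)C(O)C(O)C(C)O1
s_dox_nohoh	6-deoxy-2NH2-3OH-4OH	TRUE	[CH:1]1(O)C(N)C(O)C(O)C(C)O1
s_dox_ohhoh	6-deoxy-2OH-3deoxy-4OH	TRUE	[CH:1]1(O)C(O)CC(O)C(C)O1
s_dox_ohnmoh	6-deoxy-2OH-3NMe2-4OH	TRUE	[CH:1]1(O)C(O)C(N(C)C)C(O)C(C)O1
s_dox_ohnoh	6-deoxy-2OH-3NH2-4OH	TRUE	[CH:1]1(O)C(O)C(N)C(O)C(C)O1
s_dox_ohohh	6-deoxy-2OH-3OH-4deoxy	TRUE	[CH:1]1(O)C(O)C(O)CC(C)O1
s_dox_ohohn	6-deoxy-2OH-3OH-4NH2	TRUE	[CH:1]1(O)C(O)C(O)C(N)C(C)O1
s_dox_ohohnm	6-deoxy-2OH-3OH-4NMe2	TRUE	[CH:1]1(O)C(O)C(O)C(N(C)C)C(C)O1
s_dox_ohohom	6-deoxy-2OH-3OH-4OMe	TRUE	[CH:1]1(O)C(O)C(O)C(OC)C(C)O1
s_dox_ohomoh	6-deoxy-2OH-3OMe-4OH	TRUE	[CH:1]1(O)C(O)C(OC)C(O)C(C)O1
s_dox_omohoh	6-deoxy-2OMe-3OH-4OH	TRUE	[CH:1]1(O)C(OC)C(O)C(O)C(C)O1
s_hex_hhoh	hexose-2deoxy-3deoxy-4OH	TRUE	[CH:1]1(O)CCC(O)C(CO)O1
s_hex_hnmoh	hexose-2deoxy-3NMe2-4OH	TRUE	[CH:1]1(O)CC(N(C)C)C(O)C(CO)O1
s_hex_hnoh	hexose-2deoxy-3NH2-4OH	TRUE	[CH:1]1(O)CC(N)C(O)C(CO)O1
s_hex_hohh	hexose-2deoxy-3OH-4deoxy	TRUE	[CH:1]1(O)CC(O)CC(CO)O1
s_hex_hohn	hexose-2deoxy-3OH-4NH2	TRUE	[CH:1]1(O)CC(O)C(N)C(CO)O1
s_hex_hohnm	hexose-2deoxy-3OH-4NMe2	TRUE	[CH:1]1(O)CC(O)C(N(C)C)C(CO)O1
s_hex_hohom	hexose-2deoxy-3OH-4OMe	TRUE	[CH:1]1(O)CC(O)C(OC)C(CO)O1
s_hex_homoh	hexose-2deoxy-3OMe-4OH	TRUE	[CH:1]1(O)CC(OC)C(O)C(CO)O1
s_hex_nhoh	hexose-2NH2-3deoxy-4OH	TRUE	[CH:1]1(O)C(N)CC(O)C(CO)O1
s_hex_nmhoh	hexose-2NMe2-3deoxy-4OH	TRUE	[CH:1]1(O)C(N(C)C)CC(O)C(CO)O1
s_hex_nmohh	hexose-2NMe2-3OH-4deoxy	TRUE	[CH:1]1(O)C(N(C)C)C(O)CC(CO)O1
s_hex_nmohom	hexose-2NMe2-3OH-4OMe	FALSE	[CH:1]1(O)C(N(C)C)C(O)C(OC)C(CO)O1
s_hex_nmomoh	hexose-2NMe2-3OMe-4OH	FALSE	[CH:1]1(O)C(N(C)C)C(OC)C(O)C(CO)O1
s_hex_nohh	hexose-2NH2-3OH-4deoxy	TRUE	[CH:1]1(O)C(N)C(O)CC(CO)O1
s_hex_nohom	hexose-2NH2-3OH-4OMe	FALSE	[CH:1]1(O)C(N)C(O)C(OC)C(CO)O1
s_hex_nomoh	hexose-2NH2-3OMe-4OH	FALSE	[CH:1]1(O)C(N)C(OC)C(O)C(CO)O1
s_hex_ohhh	hexose-2OH-3deoxy-4deoxy	TRUE	[CH:1]1(O)C(O)CCC(CO)O1
s_hex_ohhn	hexose-2OH-3deoxy-4NH2	TRUE	[CH:1]1(O)C(O)CC(N)C(CO)O1
s_hex_ohhnm	hexose-2OH-3deoxy-4NMe2	TRUE	[CH:1]1(O)C(O)CC(N(C)C)C(CO)O1
s_hex_ohhom	hexose-2OH-3deoxy-4OMe	TRUE	[CH:1]1(O)C(O)CC(OC)C(CO)O1
s_hex_ohnh	hexose-2OH-3NH2-4deoxy	TRUE	[CH:1]1(O)C(O)C(N)CC(CO)O1
s_hex_ohnmh	hexose-2OH-3NMe2-4deoxy	TRUE	[CH:1]1(O)C(O)C(N(C)C)CC(CO)O1
s_hex_ohnmom	hexose-2OH-3NMe2-4OMe	FALSE	[CH:1]1(O)C(O)C(N(C)C)C(OC)C(CO)O1
s_hex_ohnom	hexose-2OH-3NH2-4OMe	FALSE	[CH:1]1(O)C(O)C(N)C(OC)C(CO)O1
s_hex_ohomh	hexose-2OH-3OMe-4deoxy	TRUE	[CH:1]1(O)C(O)C(OC)CC(CO)O1
s_hex_ohomn	hexose-2OH-3OMe-4NH2	FALSE	[CH:1]1(O)C(O)C(OC)C(N)C(CO)O1
s_hex_ohomnm	hexose-2OH-3OMe-4NMe2	FALSE	[CH:1]1(O)C(O)C(OC)C(N(C)C)C(CO)O1
s_hex_omhoh	hexose-2OMe-3deoxy-4OH	TRUE	[CH:1]1(O)C(OC)CC(O)C(CO)O1
s_hex_omnmoh	hexose-2OMe-3NMe2-4OH	FALSE	[CH:1]1(O)C(OC)C(N(C)C)C(O)C(CO)O1
s_hex_omnoh	hexose-2OMe-3NH2-4OH	FALSE	[CH:1]1(O)C(OC)C(N)C(O)C(CO)O1
s_hex_omohh	hexose-2OMe-3OH-4deoxy	TRUE	[CH:1]1(O)C(OC)C(O)CC(CO)O1
s_hex_omohn	hexose-2OMe-3OH-4NH2	FALSE	[CH:1]1(O)C(OC)C(O)C(N)C(CO)O1
s_hex_omohnm	hexose-2OMe-3OH-4NMe2	FALSE	[CH:1]1(O)C(OC)C(O)C(N(C)C)C(CO)O1
s_dox_hhoh	6-deoxy-2deoxy-3deoxy-4OH	TRUE	[CH:1]1(O)CCC(O)C(C)O1
s_dox_hnmoh	6-deoxy-2deoxy-3NMe2-4OH	TRUE	[CH:1]1(O)CC(N(C)C)C(O)C(C)O1
s_dox_hnoh	6-deoxy-2deoxy-3NH2-4OH	TRUE	[CH:1]1(O)CC(N)C(O)C(C)O1
s_dox_hohh	6-deoxy-2deoxy-3OH-4deoxy	TRUE	[CH:1]1(O)CC(O)CC(C)O1
s_dox_hohn	6-deoxy-2deoxy-3OH-4NH2	TRUE	[CH:1]1(O)CC(O)C(N)C(C)O1
s_dox_hohnm	6-deoxy-2deoxy-3OH-4NMe2	TRUE	[CH:1]1(O)CC(O)C(N(C)C)C(C)O1
s_dox_hohom	6-deoxy-2deoxy-3OH-4OMe	TRUE	[CH:1]1(O)CC(O)C(OC)C(C)O1
s_dox_homoh	6-deoxy-2deoxy-3OMe-4OH	TRUE	[CH:1]1(O)CC(OC)C(O)C(C)O1
s_dox_nhoh	6-deoxy-2NH2-3deoxy-4OH	TRUE	[CH:1]1(O)C(N)CC(O)C(C)O1
s_dox_nmhoh	6-deoxy-2NMe2-3deoxy-4OH	TRUE	[CH:1]1(O)C(N(C)C)CC(O)C(C)O1
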