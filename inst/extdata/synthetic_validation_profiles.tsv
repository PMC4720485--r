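tunnel	kind	position_A	dG_kcal_mol
Synechocystis_trHbN.STG8	well	3	-2
Synechocystis_trHbN.STG8	barrier	6	1.6
MtbN_like.LT	well	2	-2
MtbN_like.LT	barrier	5	1.5
MtbN_like.LT	well	8	-2.5
MtbN_like.LT	barrier	11	2.5
MtbN_like.LT	well	14	-1
MtbN_like.STG8	well	3	-2
MtbN_like.STG8	barrier	6	2
MtbO_like.E7G	well	3	-1.5
MtbO_like.E7G	barrier	6	2.2
MtbO_like.E7G	well	9	-1
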