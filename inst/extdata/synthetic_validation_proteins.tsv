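id	species	group	n_hbonds	ddE_O2	hexacoordinated
Synechocystis_trHbN	Synechocystis_sp	N	2	6.0	TRUE
MtbN_like	Mycobacterium_like	N	2	8.5	FALSE
MtbO_like	Mycobacterium_like	O	3	9.5	FALSE
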