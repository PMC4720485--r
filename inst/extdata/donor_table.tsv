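position	residue	donor
B10	A	FALSE
B10	C	FALSE
B10	D	FALSE
B10	E	FALSE
B10	F	FALSE
B10	G	FALSE
B10	H	TRUE
B10	I	FALSE
B10	K	TRUE
B10	L	FALSE
B10	M	FALSE
B10	N	TRUE
B10	P	FALSE
B10	Q	TRUE
B10	R	TRUE
B10	S	TRUE
B10	T	TRUE
B10	V	FALSE
B10	W	TRUE
B10	Y	TRUE
CD1	A	FALSE
CD1	C	FALSE
CD1	D	FALSE
CD1	E	FALSE
CD1	F	FALSE
CD1	G	FALSE
CD1	H	TRUE
CD1	I	FALSE
CD1	K	TRUE
CD1	L	FALSE
CD1	M	FALSE
CD1	N	TRUE
CD1	P	FALSE
CD1	Q	TRUE
CD1	R	TRUE
CD1	S	TRUE
CD1	T	TRUE
CD1	V	FALSE
CD1	W	TRUE
CD1	Y	TRUE
E11	A	FALSE
E11	C	FALSE
E11	D	FALSE
E11	E	FALSE
E11	F	FALSE
E11	G	FALSE
E11	H	TRUE
E11	I	FALSE
E11	K	TRUE
E11	L	FALSE
E11	M	FALSE
E11	N	TRUE
E11	P	FALSE
E11	Q	TRUE
E11	R	TRUE
E11	S	TRUE
E11	T	TRUE
E11	V	FALSE
E11	W	TRUE
E11	Y	TRUE
E7	A	FALSE
E7	C	FALSE
E7	D	FALSE
E7	E	FALSE
E7	F	FALSE
E7	G	FALSE
E7	H	TRUE
E7	I	FALSE
E7	K	TRUE
E7	L	FALSE
E7	M	FALSE
E7	N	TRUE
E7	P	FALSE
E7	Q	TRUE
E7	R	TRUE
E7	S	TRUE
E7	T	TRUE
E7	V	FALSE
E7	W	TRUE
E7	Y	TRUE
G8	A	FALSE
G8	C	FALSE
G8	D	FALSE
G8	E	FALSE
G8	F	FALSE
G8	G	FALSE
G8	H	TRUE
G8	I	FALSE
G8	K	TRUE
G8	L	FALSE
G8	M	FALSE
G8	N	TRUE
G8	P	FALSE
G8	Q	TRUE
G8	R	TRUE
G8	S	TRUE
G8	T	TRUE
G8	V	FALSE
G8	W	TRUE
G8	Y	TRUE
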