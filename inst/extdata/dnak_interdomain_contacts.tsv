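cluster	nbd_res	nbd_aa	sbd_res	sbd_aa	nbd_conserved	sbd_conserved
1	46	G	525	A	FALSE	FALSE
1	47	E	525	A	FALSE	FALSE
1	47	E	526	D	FALSE	FALSE
1	47	E	529	F	FALSE	FALSE
1	48	T	526	D	FALSE	FALSE
2	114	Q	515	M	FALSE	FALSE
2	160	I	512	I	TRUE	FALSE
2	160	I	515	M	TRUE	FALSE
2	160	I	516	V	TRUE	FALSE
2	160	I	519	A	TRUE	FALSE
2	161	A	516	V	FALSE	FALSE
2	161	A	519	A	FALSE	FALSE
3	74	G	506	G	TRUE	FALSE
3	98	N	505	S	FALSE	FALSE
3	100	D	505	S	FALSE	FALSE
3	149	A	505	S	FALSE	FALSE
3	149	A	506	G	FALSE	FALSE
3	153	A	506	G	TRUE	FALSE
4	148	D	483	I	TRUE	FALSE
4	148	D	484	L	TRUE	FALSE
4	151	R	483	I	TRUE	FALSE
4	152	Q	483	I	FALSE	FALSE
4	167	R	481	D	TRUE	FALSE
4	168	I	481	D	TRUE	FALSE
4	169	I	481	D	FALSE	FALSE
5	220	A	415	N	FALSE	FALSE
5	221	T	415	N	TRUE	FALSE
5	393	D	418	I	TRUE	FALSE
5	394	V	418	I	TRUE	FALSE
5	395	T	418	I	FALSE	FALSE
5	395	T	482	G	FALSE	TRUE
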