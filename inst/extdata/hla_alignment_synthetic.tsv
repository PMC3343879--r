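# Synthetic positional protein alignment for the HLA alleles used in the
# package tests and examples (1-based mature-protein coordinates).
# Position-80 Bw4-80I/Bw4-80T/Bw6 assignments and the 116Y allele set
# follow published serology; residues at other positions are realistic
# but illustrative. Not a substitute for the IMGT/HLA reference alignment.
allele	9	24	45	62	63	67	70	71	74	77	80	81	82	83	95	97	99	107	114	116	145	156
B*07:02	Y	A	E	R	N	S	N	A	D	S	N	L	R	G	I	S	Y	W	D	Y	R	L
B*08:01	Y	A	E	R	N	Y	N	A	D	S	N	L	R	G	I	S	Y	W	D	Y	L	L
B*13:02	Y	A	E	G	N	F	Q	A	D	N	I	L	L	R	I	T	Y	W	D	S	L	R
B*14:02	Y	A	E	R	N	C	K	A	D	S	N	L	R	G	I	R	F	W	D	L	L	W
B*15:01	Y	A	E	R	N	F	N	A	D	S	N	L	R	G	I	R	Y	W	D	F	L	L
B*18:01	Y	A	E	R	N	Y	N	A	D	S	N	L	R	G	I	R	Y	W	D	D	L	D
B*27:05	Y	A	E	R	N	C	K	A	D	N	T	L	L	R	I	N	F	W	D	D	L	W
B*35:01	Y	A	E	R	N	Y	N	A	D	S	N	L	R	G	I	R	Y	W	D	S	L	L
B*35:02	Y	A	E	R	N	Y	N	A	D	S	N	L	R	G	I	R	Y	W	D	Y	L	L
B*35:03	Y	A	E	R	N	Y	N	A	D	S	N	L	R	G	I	R	Y	W	D	S	L	L
B*37:01	Y	A	E	R	N	F	N	A	D	N	T	L	L	R	I	S	Y	W	D	D	L	L
B*38:01	Y	A	E	R	N	F	N	A	D	N	I	L	L	R	I	N	Y	W	D	S	L	L
B*39:01	Y	A	E	R	N	C	K	A	D	S	N	L	R	G	I	N	F	W	D	S	L	W
B*40:01	Y	A	E	E	N	S	Q	A	D	S	N	L	R	G	I	S	Y	W	D	Y	R	D
B*40:02	Y	A	E	E	N	S	Q	A	D	S	N	L	R	G	I	S	Y	W	D	Y	R	D
B*44:02	Y	A	E	E	N	F	Q	A	D	N	T	L	L	R	I	R	Y	W	D	D	L	D
B*44:03	Y	A	E	E	N	F	Q	A	D	N	T	L	L	R	I	R	Y	W	D	D	L	L
B*44:05	Y	A	E	E	N	F	Q	A	D	N	T	L	L	R	I	R	Y	W	D	Y	L	D
B*45:01	Y	A	E	E	N	S	Q	A	D	S	N	L	R	G	I	S	Y	W	D	F	L	L
B*47:01	Y	A	E	E	N	F	Q	A	D	N	T	L	L	R	I	N	Y	W	D	S	L	L
B*49:01	Y	A	E	E	N	F	Q	A	D	N	I	L	L	R	I	R	Y	W	D	D	L	L
B*50:01	Y	A	E	E	N	S	Q	A	D	S	N	L	R	G	I	S	Y	W	D	D	L	L
B*51:01	Y	A	E	L	N	F	N	A	D	N	I	L	L	R	I	S	Y	W	D	Y	L	L
B*52:01	Y	A	E	L	N	F	N	A	D	N	I	L	L	R	I	T	Y	W	D	S	L	L
B*53:01	Y	A	E	L	N	Y	N	A	D	N	I	L	L	R	I	R	Y	W	D	S	L	L
B*55:01	Y	A	E	R	N	F	N	A	D	S	N	L	R	G	I	N	Y	W	D	L	L	L
B*56:01	Y	A	E	R	N	F	N	A	D	S	N	L	R	G	I	N	Y	W	D	L	L	L
B*57:01	Y	A	E	G	N	M	S	A	D	N	I	L	L	R	I	V	Y	W	D	S	L	R
B*57:03	Y	A	E	G	N	M	S	A	D	N	I	L	L	R	I	V	Y	W	D	S	L	R
B*58:01	Y	A	E	G	N	M	S	A	D	N	I	L	L	R	I	V	Y	W	D	S	L	R
C*01:02	Y	T	G	R	E	Y	Q	A	D	S	N	L	R	G	L	R	Y	W	D	S	R	R
C*02:02	Y	T	G	R	E	Y	Q	A	D	S	K	L	R	G	L	R	Y	W	D	S	R	R
C*03:03	Y	T	G	R	E	Y	Q	A	D	S	N	L	R	G	L	S	Y	W	D	S	R	L
C*03:04	Y	T	G	R	E	Y	Q	A	D	S	N	L	R	G	L	S	Y	W	D	S	R	L
C*04:01	Y	T	G	R	E	Y	Q	A	D	S	K	L	R	G	L	R	Y	W	D	F	R	R
C*05:01	Y	T	G	R	E	Y	Q	A	D	S	K	L	R	G	L	R	Y	W	D	F	R	R
C*06:02	Y	A	G	R	E	Y	Q	A	D	S	K	L	R	G	L	W	Y	W	D	S	R	W
C*07:01	Y	S	G	R	E	Y	Q	A	D	S	N	L	R	G	L	R	Y	W	D	Y	R	L
C*07:02	Y	S	G	R	E	Y	Q	A	D	S	N	L	R	G	L	R	Y	W	D	Y	R	L
C*07:04	Y	A	G	R	E	Y	Q	A	D	S	N	L	R	G	L	W	Y	W	D	Y	R	L
C*08:02	Y	T	G	R	E	Y	Q	A	D	S	N	L	R	G	L	S	Y	W	D	S	R	R
C*12:03	Y	T	G	R	E	Y	Q	A	D	S	N	L	R	G	L	N	Y	W	D	S	R	Q
C*14:02	Y	T	G	R	E	Y	Q	A	D	S	N	L	R	G	L	R	Y	W	D	F	R	L
C*15:02	Y	T	G	R	E	Y	Q	A	D	S	K	L	R	G	L	R	Y	W	D	S	R	R
C*16:01	Y	T	G	R	E	Y	Q	A	D	S	N	L	R	G	L	N	Y	W	D	S	R	Q
A*01:01	F	A	M	Q	E	V	H	S	H	D	T	L	R	R	V	R	Y	G	H	D	H	W
A*02:01	Y	A	M	Q	E	V	H	S	H	D	T	L	R	R	V	R	Y	W	H	D	H	L
A*03:01	F	A	M	Q	E	V	H	S	H	D	T	L	R	R	V	I	Y	W	H	D	H	W
A*11:01	F	A	M	Q	E	V	H	S	H	D	T	L	R	R	V	I	Y	G	H	D	H	W
A*24:02	Y	A	M	Q	E	V	H	S	H	D	T	L	R	R	V	R	Y	W	H	D	H	Q
A*26:01	F	A	M	Q	E	V	H	S	H	D	T	L	R	R	V	R	Y	G	H	D	H	W
A*29:02	F	A	M	Q	E	V	H	S	H	D	T	L	R	R	V	R	Y	W	H	D	H	W
A*32:01	F	A	M	Q	E	V	H	S	H	D	T	L	R	R	V	R	Y	W	H	D	H	W
DQA1*01:01	Y	A	E	G	G	G	Q	G	G	G	G	G	G	G	G	S	G	G	G	G	G	G
DQA1*01:02	F	T	K	G	G	G	R	G	G	G	G	G	G	G	G	N	G	G	G	G	G	G
DQA1*02:01	S	A	Q	G	G	G	D	G	G	G	G	G	G	G	G	S	G	G	G	G	G	G
DQA1*03:01	L	T	E	G	G	G	Q	G	G	G	G	G	G	G	G	N	G	G	G	G	G	G
DQA1*05:01	W	A	K	G	G	G	R	G	G	G	G	G	G	G	G	S	G	G	G	G	G	G
DQB1*02:01	Y	A	E	G	G	G	Q	G	G	G	G	G	G	G	G	S	G	G	G	G	G	G
DQB1*02:02	F	T	K	G	G	G	R	G	G	G	G	G	G	G	G	N	G	G	G	G	G	G
DQB1*03:01	S	A	Q	G	G	G	D	G	G	G	G	G	G	G	G	S	G	G	G	G	G	G
DQB1*03:02	L	T	E	G	G	G	Q	G	G	G	G	G	G	G	G	N	G	G	G	G	G	G
DQB1*03:03	W	A	K	G	G	G	R	G	G	G	G	G	G	G	G	S	G	G	G	G	G	G
DQB1*05:01	C	T	Q	G	G	G	D	G	G	G	G	G	G	G	G	N	G	G	G	G	G	G
DQB1*05:02	V	A	E	G	G	G	Q	G	G	G	G	G	G	G	G	S	G	G	G	G	G	G
DQB1*06:02	T	T	K	G	G	G	R	G	G	G	G	G	G	G	G	N	G	G	G	G	G	G
DQB1*06:04	E	A	Q	G	G	G	D	G	G	G	G	G	G	G	G	S	G	G	G	G	G	G
DRB1*01:01	Y	A	E	G	G	G	Q	G	G	G	G	G	G	G	G	S	G	G	G	G	G	G
DRB1*03:01	F	T	K	G	G	G	R	G	G	G	G	G	G	G	G	N	G	G	G	G	G	G
DRB1*04:04	S	A	Q	G	G	G	D	G	G	G	G	G	G	G	G	S	G	G	G	G	G	G
DRB1*07:01	L	T	E	G	G	G	Q	G	G	G	G	G	G	G	G	N	G	G	G	G	G	G
DRB1*13:02	W	A	K	G	G	G	R	G	G	G	G	G	G	G	G	S	G	G	G	G	G	G
DRB1*15:01	C	T	Q	G	G	G	D	G	G	G	G	G	G	G	G	N	G	G	G	G	G	G
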