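# Elongator tRNA isoacceptors of E. coli K-12 with anticodons (5'->3').
# Initiator Met and selenocysteine tRNA are omitted: they take no part in
# elongation. A34 is read as inosine; Ile2's C34 is lysidine (reads AUA).
name	amino_acid	anticodon
Ala1B	A	UGC
Ala2	A	GGC
Arg2	R	ACG
Arg3	R	CCG
Arg4	R	UCU
Arg5	R	CCU
Asn	N	GUU
Asp1	D	GUC
Cys	C	GCA
Gln1	Q	UUG
Gln2	Q	CUG
Glu2	E	UUC
Gly1	G	CCC
Gly2	G	UCC
Gly3	G	GCC
His	H	GUG
Ile1	I	GAU
Ile2	I	CAU
Leu1	L	CAG
Leu2	L	GAG
Leu3	L	UAG
Leu4	L	CAA
Leu5	L	UAA
Lys	K	UUU
Met	M	CAU
Phe	F	GAA
Pro1	P	CGG
Pro2	P	GGG
Pro3	P	UGG
Ser1	S	UGA
Ser2	S	CGA
Ser3	S	GCU
Ser5	S	GGA
Thr1	T	GGU
Thr2	T	CGU
Thr3	T	GGU
Thr4	T	UGU
Trp	W	CCA
Tyr1	Y	GUA
Tyr2	Y	GUA
Val1	V	UAC
Val2A	V	GAC
Val2B	V	GAC
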