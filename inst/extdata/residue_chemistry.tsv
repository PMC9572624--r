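resname	atom	role	hcount	antecedents	rotatable
ALA	N	donor	1	CA	0
ALA	O	acceptor		C	0
ARG	N	donor	1	CA	0
ARG	O	acceptor		C	0
ARG	NE	donor	1		0
ARG	NH1	donor	2		0
ARG	NH2	donor	2		0
ARG	NE	charged			0
ARG	NH1	charged			0
ARG	NH2	charged			0
ASN	N	donor	1	CA	0
ASN	O	acceptor		C	0
ASN	ND2	donor	2		0
ASN	OD1	acceptor		CG	0
ASP	N	donor	1	CA	0
ASP	O	acceptor		C	0
ASP	OD1	acceptor		CG	0
ASP	OD2	acceptor		CG	0
ASP	OD1	charged			0
ASP	OD2	charged			0
CYS	N	donor	1	CA	0
CYS	O	acceptor		C	0
CYS	SG	donor	1		1
GLN	N	donor	1	CA	0
GLN	O	acceptor		C	0
GLN	NE2	donor	2		0
GLN	OE1	acceptor		CD	0
GLU	N	donor	1	CA	0
GLU	O	acceptor		C	0
GLU	OE1	acceptor		CD	0
GLU	OE2	acceptor		CD	0
GLU	OE1	charged			0
GLU	OE2	charged			0
GLY	N	donor	1	CA	0
GLY	O	acceptor		C	0
HIS	N	donor	1	CA	0
HIS	O	acceptor		C	0
HIS	ND1	donor	1		0
HIS	NE2	donor	1		0
HIS	ND1	charged			0
HIS	NE2	charged			0
ILE	N	donor	1	CA	0
ILE	O	acceptor		C	0
LEU	N	donor	1	CA	0
LEU	O	acceptor		C	0
LYS	N	donor	1	CA	0
LYS	O	acceptor		C	0
LYS	NZ	donor	3		0
LYS	NZ	charged			0
MET	N	donor	1	CA	0
MET	O	acceptor		C	0
MET	SD	acceptor		CG,CE	0
PHE	N	donor	1	CA	0
PHE	O	acceptor		C	0
PRO	O	acceptor		C	0
SER	N	donor	1	CA	0
SER	O	acceptor		C	0
SER	OG	donor	1		1
SER	OG	acceptor		CB	0
THR	N	donor	1	CA	0
THR	O	acceptor		C	0
THR	OG1	donor	1		1
THR	OG1	acceptor		CB	0
TRP	N	donor	1	CA	0
TRP	O	acceptor		C	0
TRP	NE1	donor	1		0
TYR	N	donor	1	CA	0
TYR	O	acceptor		C	0
TYR	OH	donor	1		1
TYR	OH	acceptor		CZ	0
VAL	N	donor	1	CA	0
VAL	O	acceptor		C	0
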