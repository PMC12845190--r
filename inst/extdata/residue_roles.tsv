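resname	role	atoms
ALA	donor	N:H
ALA	acceptor	O
ALA	apolar	CB
GLY	donor	N:H
GLY	acceptor	O
SER	donor	N:H,OG:HG
SER	acceptor	O,OG
SER	apolar	CB
THR	donor	N:H,OG1:HG1
THR	acceptor	O,OG1
THR	apolar	CG2
CYS	donor	N:H
CYS	acceptor	O
CYS	apolar	CB,SG
VAL	donor	N:H
VAL	acceptor	O
VAL	apolar	CB,CG1,CG2
LEU	donor	N:H
LEU	acceptor	O
LEU	apolar	CB,CG,CD1,CD2
ILE	donor	N:H
ILE	acceptor	O
ILE	apolar	CB,CG1,CG2,CD1
MET	donor	N:H
MET	acceptor	O
MET	apolar	CB,CG,SD,CE
PRO	acceptor	O
PRO	apolar	CB,CG
PHE	donor	N:H
PHE	acceptor	O
PHE	ring	CG,CD1,CD2,CE1,CE2,CZ
PHE	apolar	CB
TYR	donor	N:H,OH:HH
TYR	acceptor	O,OH
TYR	ring	CG,CD1,CD2,CE1,CE2,CZ
TYR	apolar	CB
TRP	donor	N:H,NE1:HE1
TRP	acceptor	O
TRP	ring	CG,CD1,NE1,CE2,CD2
TRP	ring	CE2,CD2,CE3,CZ3,CH2,CZ2
TRP	apolar	CB
HIS	donor	N:H,ND1:HD1,NE2:HE2
HIS	acceptor	O,ND1,NE2
HIS	ring	CG,ND1,CD2,CE1,NE2
HIS	apolar	CB
ASP	donor	N:H
ASP	acceptor	O,OD1,OD2
ASP	anion	OD1,OD2
ASP	apolar	CB
GLU	donor	N:H
GLU	acceptor	O,OE1,OE2
GLU	anion	OE1,OE2
GLU	apolar	CB,CG
ASN	donor	N:H,ND2:HD21,ND2:HD22
ASN	acceptor	O,OD1
ASN	apolar	CB
GLN	donor	N:H,NE2:HE21,NE2:HE22
GLN	acceptor	O,OE1
GLN	apolar	CB,CG
LYS	donor	N:H,NZ:HZ1,NZ:HZ2,NZ:HZ3
LYS	acceptor	O
LYS	cation	NZ
LYS	apolar	CB,CG,CD
ARG	donor	N:H,NE:HE,NH1:HH11,NH1:HH12,NH2:HH21,NH2:HH22
ARG	acceptor	O
ARG	cation	NE,NH1,NH2,CZ
ARG	apolar	CB,CG
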