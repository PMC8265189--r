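# United-atom van der Waals radii (Angstrom), reconstructed from the ProtOr/NucProt united-atom class scheme (chemical class + bound hydrogens); not the original published per-type fits.
# Classes used: C3H0 1.61, C3H1 1.76, C4Hn 1.88, N 1.64, O1H0 1.42, O2H1/O2H2/ester O 1.46, S 1.77, P 2.04.
# .ELEMENT rows are per-element fallbacks; .DEFAULT is the generic default radius.
res_name	atom_name	radius
ALA	N	1.64
ALA	CA	1.88
ALA	C	1.61
ALA	O	1.42
ALA	OXT	1.46
ALA	CB	1.88
ARG	N	1.64
ARG	CA	1.88
ARG	C	1.61
ARG	O	1.42
ARG	OXT	1.46
ARG	CB	1.88
ARG	CG	1.88
ARG	CD	1.88
ARG	NE	1.64
ARG	CZ	1.61
ARG	NH1	1.64
ARG	NH2	1.64
ASN	N	1.64
ASN	CA	1.88
ASN	C	1.61
ASN	O	1.42
ASN	OXT	1.46
ASN	CB	1.88
ASN	CG	1.61
ASN	OD1	1.42
ASN	ND2	1.64
ASP	N	1.64
ASP	CA	1.88
ASP	C	1.61
ASP	O	1.42
ASP	OXT	1.46
ASP	CB	1.88
ASP	CG	1.61
ASP	OD1	1.42
ASP	OD2	1.42
CYS	N	1.64
CYS	CA	1.88
CYS	C	1.61
CYS	O	1.42
CYS	OXT	1.46
CYS	CB	1.88
CYS	SG	1.77
GLN	N	1.64
GLN	CA	1.88
GLN	C	1.61
GLN	O	1.42
GLN	OXT	1.46
GLN	CB	1.88
GLN	CG	1.88
GLN	CD	1.61
GLN	OE1	1.42
GLN	NE2	1.64
GLU	N	1.64
GLU	CA	1.88
GLU	C	1.61
GLU	O	1.42
GLU	OXT	1.46
GLU	CB	1.88
GLU	CG	1.88
GLU	CD	1.61
GLU	OE1	1.42
GLU	OE2	1.42
GLY	N	1.64
GLY	CA	1.88
GLY	C	1.61
GLY	O	1.42
GLY	OXT	1.46
HIS	N	1.64
HIS	CA	1.88
HIS	C	1.61
HIS	O	1.42
HIS	OXT	1.46
HIS	CB	1.88
HIS	CG	1.61
HIS	ND1	1.64
HIS	CD2	1.76
HIS	CE1	1.76
HIS	NE2	1.64
ILE	N	1.64
ILE	CA	1.88
ILE	C	1.61
ILE	O	1.42
ILE	OXT	1.46
ILE	CB	1.88
ILE	CG1	1.88
ILE	CG2	1.88
ILE	CD1	1.88
LEU	N	1.64
LEU	CA	1.88
LEU	C	1.61
LEU	O	1.42
LEU	OXT	1.46
LEU	CB	1.88
LEU	CG	1.88
LEU	CD1	1.88
LEU	CD2	1.88
LYS	N	1.64
LYS	CA	1.88
LYS	C	1.61
LYS	O	1.42
LYS	OXT	1.46
LYS	CB	1.88
LYS	CG	1.88
LYS	CD	1.88
LYS	CE	1.88
LYS	NZ	1.64
MET	N	1.64
MET	CA	1.88
MET	C	1.61
MET	O	1.42
MET	OXT	1.46
MET	CB	1.88
MET	CG	1.88
MET	SD	1.77
MET	CE	1.88
PHE	N	1.64
PHE	CA	1.88
PHE	C	1.61
PHE	O	1.42
PHE	OXT	1.46
PHE	CB	1.88
PHE	CG	1.61
PHE	CD1	1.76
PHE	CD2	1.76
PHE	CE1	1.76
PHE	CE2	1.76
PHE	CZ	1.76
PRO	N	1.64
PRO	CA	1.88
PRO	C	1.61
PRO	O	1.42
PRO	OXT	1.46
PRO	CB	1.88
PRO	CG	1.88
PRO	CD	1.88
SER	N	1.64
SER	CA	1.88
SER	C	1.61
SER	O	1.42
SER	OXT	1.46
SER	CB	1.88
SER	OG	1.46
THR	N	1.64
THR	CA	1.88
THR	C	1.61
THR	O	1.42
THR	OXT	1.46
THR	CB	1.88
THR	OG1	1.46
THR	CG2	1.88
TRP	N	1.64
TRP	CA	1.88
TRP	C	1.61
TRP	O	1.42
TRP	OXT	1.46
TRP	CB	1.88
TRP	CG	1.61
TRP	CD1	1.76
TRP	CD2	1.61
TRP	NE1	1.64
TRP	CE2	1.61
TRP	CE3	1.76
TRP	CZ2	1.76
TRP	CZ3	1.76
TRP	CH2	1.76
TYR	N	1.64
TYR	CA	1.88
TYR	C	1.61
TYR	O	1.42
TYR	OXT	1.46
TYR	CB	1.88
TYR	CG	1.61
TYR	CD1	1.76
TYR	CD2	1.76
TYR	CE1	1.76
TYR	CE2	1.76
TYR	CZ	1.61
TYR	OH	1.46
VAL	N	1.64
VAL	CA	1.88
VAL	C	1.61
VAL	O	1.42
VAL	OXT	1.46
VAL	CB	1.88
VAL	CG1	1.88
VAL	CG2	1.88
A	P	2.04
A	OP1	1.46
A	OP2	1.46
A	OP3	1.46
A	O1P	1.46
A	O2P	1.46
A	O5'	1.46
A	C5'	1.88
A	C4'	1.88
A	O4'	1.46
A	C3'	1.88
A	O3'	1.46
A	C2'	1.88
A	O2'	1.46
A	C1'	1.88
A	N9	1.64
A	C8	1.76
A	N7	1.64
A	C5	1.61
A	C6	1.61
A	N6	1.64
A	N1	1.64
A	C2	1.76
A	N3	1.64
A	C4	1.61
G	P	2.04
G	OP1	1.46
G	OP2	1.46
G	OP3	1.46
G	O1P	1.46
G	O2P	1.46
G	O5'	1.46
G	C5'	1.88
G	C4'	1.88
G	O4'	1.46
G	C3'	1.88
G	O3'	1.46
G	C2'	1.88
G	O2'	1.46
G	C1'	1.88
G	N9	1.64
G	C8	1.76
G	N7	1.64
G	C5	1.61
G	C6	1.61
G	O6	1.42
G	N1	1.64
G	C2	1.61
G	N2	1.64
G	N3	1.64
G	C4	1.61
C	P	2.04
C	OP1	1.46
C	OP2	1.46
C	OP3	1.46
C	O1P	1.46
C	O2P	1.46
C	O5'	1.46
C	C5'	1.88
C	C4'	1.88
C	O4'	1.46
C	C3'	1.88
C	O3'	1.46
C	C2'	1.88
C	O2'	1.46
C	C1'	1.88
C	N1	1.64
C	C2	1.61
C	O2	1.42
C	N3	1.64
C	C4	1.61
C	N4	1.64
C	C5	1.76
C	C6	1.76
U	P	2.04
U	OP1	1.46
U	OP2	1.46
U	OP3	1.46
U	O1P	1.46
U	O2P	1.46
U	O5'	1.46
U	C5'	1.88
U	C4'	1.88
U	O4'	1.46
U	C3'	1.88
U	O3'	1.46
U	C2'	1.88
U	O2'	1.46
U	C1'	1.88
U	N1	1.64
U	C2	1.61
U	O2	1.42
U	N3	1.64
U	C4	1.61
U	O4	1.42
U	C5	1.76
U	C6	1.76
DA	P	2.04
DA	OP1	1.46
DA	OP2	1.46
DA	OP3	1.46
DA	O1P	1.46
DA	O2P	1.46
DA	O5'	1.46
DA	C5'	1.88
DA	C4'	1.88
DA	O4'	1.46
DA	C3'	1.88
DA	O3'	1.46
DA	C2'	1.88
DA	O2'	1.46
DA	C1'	1.88
DA	N9	1.64
DA	C8	1.76
DA	N7	1.64
DA	C5	1.61
DA	C6	1.61
DA	N6	1.64
DA	N1	1.64
DA	C2	1.76
DA	N3	1.64
DA	C4	1.61
DG	P	2.04
DG	OP1	1.46
DG	OP2	1.46
DG	OP3	1.46
DG	O1P	1.46
DG	O2P	1.46
DG	O5'	1.46
DG	C5'	1.88
DG	C4'	1.88
DG	O4'	1.46
DG	C3'	1.88
DG	O3'	1.46
DG	C2'	1.88
DG	O2'	1.46
DG	C1'	1.88
DG	N9	1.64
DG	C8	1.76
DG	N7	1.64
DG	C5	1.61
DG	C6	1.61
DG	O6	1.42
DG	N1	1.64
DG	C2	1.61
DG	N2	1.64
DG	N3	1.64
DG	C4	1.61
DC	P	2.04
DC	OP1	1.46
DC	OP2	1.46
DC	OP3	1.46
DC	O1P	1.46
DC	O2P	1.46
DC	O5'	1.46
DC	C5'	1.88
DC	C4'	1.88
DC	O4'	1.46
DC	C3'	1.88
DC	O3'	1.46
DC	C2'	1.88
DC	O2'	1.46
DC	C1'	1.88
DC	N1	1.64
DC	C2	1.61
DC	O2	1.42
DC	N3	1.64
DC	C4	1.61
DC	N4	1.64
DC	C5	1.76
DC	C6	1.76
DT	P	2.04
DT	OP1	1.46
DT	OP2	1.46
DT	OP3	1.46
DT	O1P	1.46
DT	O2P	1.46
DT	O5'	1.46
DT	C5'	1.88
DT	C4'	1.88
DT	O4'	1.46
DT	C3'	1.88
DT	O3'	1.46
DT	C2'	1.88
DT	O2'	1.46
DT	C1'	1.88
DT	N1	1.64
DT	C2	1.61
DT	O2	1.42
DT	N3	1.64
DT	C4	1.61
DT	O4	1.42
DT	C5	1.61
DT	C6	1.76
DT	C7	1.88
DT	C5M	1.88
HOH	O	1.46
.ELEMENT	C	1.88
.ELEMENT	N	1.64
.ELEMENT	O	1.46
.ELEMENT	S	1.77
.ELEMENT	P	2.04
.ELEMENT	SE	1.9
.ELEMENT	F	1.47
.ELEMENT	CL	1.75
.ELEMENT	BR	1.85
.ELEMENT	I	1.98
.DEFAULT	*	1.7
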