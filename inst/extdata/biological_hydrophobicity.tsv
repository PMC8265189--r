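# Biological (membrane-insertion) hydrophobicity scale: apparent free energy of membrane insertion per residue (kcal/mol).
# Class cutoffs used by the engine: < 0 hydrophobic; [0, 1.45] medium polar; > 1.45 polar.
# 1.45 is the midpoint of the gap between SER (0.84) and ASN (2.05).
res_name	value
ALA	0.11
CYS	-0.13
ASP	3.49
GLU	2.68
PHE	-0.32
GLY	0.74
HIS	2.06
ILE	-0.6
LYS	2.71
LEU	-0.55
MET	-0.1
ASN	2.05
PRO	2.23
GLN	2.36
ARG	2.58
SER	0.84
THR	0.52
VAL	-0.31
TRP	0.3
TYR	0.68
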