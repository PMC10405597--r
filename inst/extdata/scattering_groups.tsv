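# United-atom scattering groups, version 1.
# electrons include implicit hydrogens folded into the parent heavy atom.
# radius: atomic-group radius (Å); solvent-displaced electrons b0 = 10*(radius/1.93)^3.
residue	atom	group	electrons	radius
ALA	N	NH	8	1.65
ALA	CA	CH	7	1.9
ALA	C	C	6	1.7
ALA	O	O	8	1.5
ALA	OXT	O	8	1.5
ALA	CB	CH3	9	2
ARG	N	NH	8	1.65
ARG	CA	CH	7	1.9
ARG	C	C	6	1.7
ARG	O	O	8	1.5
ARG	OXT	O	8	1.5
ARG	CB	CH2	8	1.9
ARG	CG	CH2	8	1.9
ARG	CD	CH2	8	1.9
ARG	NE	NH	8	1.65
ARG	CZ	C	6	1.7
ARG	NH1	NH2	9	1.7
ARG	NH2	NH2	9	1.7
ASN	N	NH	8	1.65
ASN	CA	CH	7	1.9
ASN	C	C	6	1.7
ASN	O	O	8	1.5
ASN	OXT	O	8	1.5
ASN	CB	CH2	8	1.9
ASN	CG	C	6	1.7
ASN	OD1	O	8	1.5
ASN	ND2	NH2	9	1.7
ASP	N	NH	8	1.65
ASP	CA	CH	7	1.9
ASP	C	C	6	1.7
ASP	O	O	8	1.5
ASP	OXT	O	8	1.5
ASP	CB	CH2	8	1.9
ASP	CG	C	6	1.7
ASP	OD1	O	8	1.5
ASP	OD2	O	8	1.5
CYS	N	NH	8	1.65
CYS	CA	CH	7	1.9
CYS	C	C	6	1.7
CYS	O	O	8	1.5
CYS	OXT	O	8	1.5
CYS	CB	CH2	8	1.9
CYS	SG	SH	17	1.85
GLN	N	NH	8	1.65
GLN	CA	CH	7	1.9
GLN	C	C	6	1.7
GLN	O	O	8	1.5
GLN	OXT	O	8	1.5
GLN	CB	CH2	8	1.9
GLN	CG	CH2	8	1.9
GLN	CD	C	6	1.7
GLN	OE1	O	8	1.5
GLN	NE2	NH2	9	1.7
GLU	N	NH	8	1.65
GLU	CA	CH	7	1.9
GLU	C	C	6	1.7
GLU	O	O	8	1.5
GLU	OXT	O	8	1.5
GLU	CB	CH2	8	1.9
GLU	CG	CH2	8	1.9
GLU	CD	C	6	1.7
GLU	OE1	O	8	1.5
GLU	OE2	O	8	1.5
GLY	N	NH	8	1.65
GLY	CA	CH2	8	1.9
GLY	C	C	6	1.7
GLY	O	O	8	1.5
GLY	OXT	O	8	1.5
HIS	N	NH	8	1.65
HIS	CA	CH	7	1.9
HIS	C	C	6	1.7
HIS	O	O	8	1.5
HIS	OXT	O	8	1.5
HIS	CB	CH2	8	1.9
HIS	CG	C	6	1.7
HIS	ND1	NH	8	1.65
HIS	CD2	CH	7	1.9
HIS	CE1	CH	7	1.9
HIS	NE2	N	7	1.6
ILE	N	NH	8	1.65
ILE	CA	CH	7	1.9
ILE	C	C	6	1.7
ILE	O	O	8	1.5
ILE	OXT	O	8	1.5
ILE	CB	CH	7	1.9
ILE	CG1	CH2	8	1.9
ILE	CG2	CH3	9	2
ILE	CD1	CH3	9	2
LEU	N	NH	8	1.65
LEU	CA	CH	7	1.9
LEU	C	C	6	1.7
LEU	O	O	8	1.5
LEU	OXT	O	8	1.5
LEU	CB	CH2	8	1.9
LEU	CG	CH	7	1.9
LEU	CD1	CH3	9	2
LEU	CD2	CH3	9	2
LYS	N	NH	8	1.65
LYS	CA	CH	7	1.9
LYS	C	C	6	1.7
LYS	O	O	8	1.5
LYS	OXT	O	8	1.5
LYS	CB	CH2	8	1.9
LYS	CG	CH2	8	1.9
LYS	CD	CH2	8	1.9
LYS	CE	CH2	8	1.9
LYS	NZ	NH3	10	1.8
MET	N	NH	8	1.65
MET	CA	CH	7	1.9
MET	C	C	6	1.7
MET	O	O	8	1.5
MET	OXT	O	8	1.5
MET	CB	CH2	8	1.9
MET	CG	CH2	8	1.9
MET	SD	S	16	1.8
MET	CE	CH3	9	2
PHE	N	NH	8	1.65
PHE	CA	CH	7	1.9
PHE	C	C	6	1.7
PHE	O	O	8	1.5
PHE	OXT	O	8	1.5
PHE	CB	CH2	8	1.9
PHE	CG	C	6	1.7
PHE	CD1	CH	7	1.9
PHE	CD2	CH	7	1.9
PHE	CE1	CH	7	1.9
PHE	CE2	CH	7	1.9
PHE	CZ	CH	7	1.9
PRO	N	N	7	1.6
PRO	CA	CH	7	1.9
PRO	C	C	6	1.7
PRO	O	O	8	1.5
PRO	OXT	O	8	1.5
PRO	CB	CH2	8	1.9
PRO	CG	CH2	8	1.9
PRO	CD	CH2	8	1.9
SER	N	NH	8	1.65
SER	CA	CH	7	1.9
SER	C	C	6	1.7
SER	O	O	8	1.5
SER	OXT	O	8	1.5
SER	CB	CH2	8	1.9
SER	OG	OH	9	1.6
THR	N	NH	8	1.65
THR	CA	CH	7	1.9
THR	C	C	6	1.7
THR	O	O	8	1.5
THR	OXT	O	8	1.5
THR	CB	CH	7	1.9
THR	OG1	OH	9	1.6
THR	CG2	CH3	9	2
TRP	N	NH	8	1.65
TRP	CA	CH	7	1.9
TRP	C	C	6	1.7
TRP	O	O	8	1.5
TRP	OXT	O	8	1.5
TRP	CB	CH2	8	1.9
TRP	CG	C	6	1.7
TRP	CD1	CH	7	1.9
TRP	CD2	C	6	1.7
TRP	NE1	NH	8	1.65
TRP	CE2	C	6	1.7
TRP	CE3	CH	7	1.9
TRP	CZ2	CH	7	1.9
TRP	CZ3	CH	7	1.9
TRP	CH2	CH	7	1.9
TYR	N	NH	8	1.65
TYR	CA	CH	7	1.9
TYR	C	C	6	1.7
TYR	O	O	8	1.5
TYR	OXT	O	8	1.5
TYR	CB	CH2	8	1.9
TYR	CG	C	6	1.7
TYR	CD1	CH	7	1.9
TYR	CD2	CH	7	1.9
TYR	CE1	CH	7	1.9
TYR	CE2	CH	7	1.9
TYR	CZ	C	6	1.7
TYR	OH	OH	9	1.6
VAL	N	NH	8	1.65
VAL	CA	CH	7	1.9
VAL	C	C	6	1.7
VAL	O	O	8	1.5
VAL	OXT	O	8	1.5
VAL	CB	CH	7	1.9
VAL	CG1	CH3	9	2
VAL	CG2	CH3	9	2
BEA	CA	BEAD	54	3
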