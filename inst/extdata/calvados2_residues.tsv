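# One-bead-per-residue parameters for the CALVADOS 2 coarse-grained force
# field, re-typed from the published force-field description (Tesei &
# Lindorff-Larsen, CALVADOS 2).  sigma in nm, mass in amu, charge in
# elementary charges at neutral pH (His handled by Henderson-Hasselbalch at
# run time), kd = Kyte-Doolittle hydropathy.
code	three	mass	sigma	lambda	charge	pka	kd
A	ALA	71.08	0.504	0.2743297969040348	0	NA	1.8
R	ARG	156.19	0.656	0.7307624767517166	1	NA	-4.5
N	ASN	114.10	0.568	0.4255859009787431	0	NA	-3.5
D	ASP	115.09	0.558	0.0416040480605567	-1	NA	-3.5
C	CYS	103.14	0.548	0.5615435099141777	0	NA	2.5
Q	GLN	128.13	0.602	0.3934318551056041	0	NA	-3.5
E	GLU	129.12	0.592	0.0006935460962935	-1	NA	-3.5
G	GLY	57.05	0.450	0.7058843733666401	0	NA	-0.4
H	HIS	137.14	0.608	0.4663667290557992	0	6.0	-3.2
I	ILE	113.16	0.618	0.5423623610671892	0	NA	4.5
L	LEU	113.16	0.618	0.6440005007782226	0	NA	3.8
K	LYS	128.17	0.636	0.1790211738990582	1	NA	-3.9
M	MET	131.20	0.618	0.5308481134337497	0	NA	1.9
F	PHE	147.18	0.636	0.8672358982062975	0	NA	2.8
P	PRO	97.12	0.556	0.3593126576364644	0	NA	-1.6
S	SER	87.08	0.518	0.4625416811611541	0	NA	-0.8
T	THR	101.10	0.562	0.3713162976273964	0	NA	-0.7
W	TRP	186.21	0.678	0.9893764740371644	0	NA	-0.9
Y	TYR	163.18	0.646	0.9774611449343455	0	NA	-1.3
V	VAL	99.13	0.586	0.2083769608174481	0	NA	4.2
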