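C(=O)O[C,H1].C(=O)O[C,H1].C(=O)O[C,H1]	> 2 ester groups
n1c([F,Cl,Br,I])cccc1	2-halo pyridine
C(=O)[Cl,Br,I,F]	acid halide
C=[C!r]O	acyclic C=C-O
N#CC(=O)	acyl cyanide
C(=O)N[NH2]	acyl hydrazine
[CH1](=O)	aldehyde
[R0;D2][R0;D2][R0;D2][R0;D2]	Aliphatic long chain
[CX4][Cl,Br,I]	alkyl halide
c1nnnn1C=O	amidotetrazole
c1cc([NH2])ccc1	aniline
[CH2R2]1N[CH2R2][CH2R2][CH2R2][CH2R2][CH2R2]1	azepane
N=[N+]=[N-]	Azido group
N#N	Azo group
[CH2R2]1N[CH2R2][CH2R2][CH2R2][CH2R2][CH2R2][CH2R2]1	azocane
[cR2]1[cR2][cR2]([Nv3X3,Nv4X4])[cR2][cR2][cR2]1[cR2]2[cR2][cR2][cR2]([Nv3X3,Nv4X4])[cR2][cR2]2	benzidine
[C,c](=O)[CX4,CR0X3,O][C,c](=O)	beta-keto/anhydride
C12C(NC(N1)=O)CSC2	biotin analogue
[C+,c+,C-,c-]	Carbocation/anion
c1c([OH])c([OH,NH2,NH])ccc1	catechol
[O+,o+,S+,s+]	charged oxygen or sulfur atoms
C1(=[O,N])C=CC(=[O,N])C=C1	chinone 1
C1(=[O,N])C(=[O,N])C=CC=C1	chinone 2
C=[C!r]C#N	conjugated nitrile group
[OR2,NR2]@[CR2]@[CR2]@[OR2,NR2]@[CR2]@[CR2]@[OR2,NR2]	crown ether
c1ccc2c(c1)ccc(=O)o2	cumarine
N[CH2]C#N	cyanamide
[N,O,S]C#N	cyanate/aminonitrile/thiocyanate
N#CC[OH]	cyanohydrins
[CR2]1[CR2][CR2][CR2][CR2][CR2][CR2]1	cycloheptane 1
[CR2]1[CR2][CR2]cc[CR2][CR2]1	cycloheptane 2
[CR2]1[CR2][CR2][CR2][CR2][CR2][CR2][CR2]1	cyclooctane 1
[CR2]1[CR2][CR2]cc[CR2][CR2][CR2]1	cyclooctane 2
[cR2]1[cR2]c([N+0X3R0,nX3R0])c([N+0X3R0,nX3R0])[cR2][cR2]1	diaminobenzene 1
[cR2]1[cR2]c([N+0X3R0,nX3R0])[cR2]c([N+0X3R0,nX3R0])[cR2]1	diaminobenzene 2
[cR2]1[cR2]c([N+0X3R0,nX3R0])[cR2][cR2]c1([N+0X3R0,nX3R0])	diaminobenzene 3
[N!R]=[N!R]	diazo group
[C,c](=O)[C,c](=O)	diketo group
SS	disulphide
[CX2R0][NX3R0]	enamine
C(=O)Onnn	ester of HOBT
C1(=O)OCC1	four member lactones
c1cc([Cl,Br,I,F])cc([Cl,Br,I,F])c1[Cl,Br,I,F]	halogenated ring 1
c1ccc([Cl,Br,I,F])c([Cl,Br,I,F])c1[Cl,Br,I,F]	halogenated ring 2
[Hg,Fe,As,Sb,Zn,Se,se,Te,B,Si]	heavy metal
[NX3R0,NX4R0,OR0,SX2R0][CX4][NX3R0,NX4R0,OR0,SX2R0]	het-C-het not in ring
C1NC(=O)NC(=O)1	hydantoin
N[NH2]	hydrazine
[OH]c1ccc([OH,NH2,NH])cc1	hydroquinone
C(=O)N[OH]	hydroxamic acid
C=[N!R]	imine 1
N=[CR0][N,n,O,S]	imine 2
I	iodine
N=C=O	isocyanate
[$([CH2]),$([CH][CX4]),$(C([CX4])[CX4])]=[$([CH2]),$([CH][CX4]),$(C([CX4])[CX4])]	isolated alkene
C=C=O	ketene
S1C=CSC1=S	methylidene-1,3-dithiole
C=!@CC=[O,S]	Michael acceptor 1
[$([CH]),$(CC)]#CC(=O)[C,c]	Michael acceptor 2
[$([CH]),$(CC)]#CS(=O)(=O)[C,c]	Michael acceptor 3
C=C(C=O)C=O	Michael acceptor 4
[$([CH]),$(CC)]#CC(=O)O[C,c]	Michael acceptor 5
[NX2,nX3][OX1]	N oxide
s1c(S)nnc1NC=O	N-acyl-2-amino-5-mercapto-1,3,4-thiadiazole
NC[F,Cl,Br,I]	N-C-halo
[NX3,NX4][F,Cl,Br,I]	N-halo
n[OH]	N-hydroxyl pyridine
[N+](=O)[O-]	nitro group
[#7]-N=O	N-nitroso
[C,c]=N[OH]	oxime 1
[C,c]=NOC=O	oxime 2
[OR0,NR0][OR0,NR0]	Oxygen-nitrogen single bond
[CX4](F)(F)[CX4](F)F	perfluorinated chain
OO	peroxide
c1ccccc1OC(=O)[#6]	phenol ester
c1ccccc1OC(=O)O	phenyl carbonate
P	phosphor
[cR,CR]~C(=O)NC(=O)~[cR,CR]	phthalimide
a1aa2a3a(a1)A=AA=A3=AA=A2	Polycyclic aromatic hydrocarbon 1
a21aa3a(aa1aaaa2)aaaa3	Polycyclic aromatic hydrocarbon 2
a31a(a2a(aa1)aaaa2)aaaa3	Polycyclic aromatic hydrocarbon 3
[CR0]=[CR0][CR0]=[CR0]	polyene
[s,S,c,C,n,N,o,O]~[nX3+,NX3+](~[s,S,c,C,n,N])~[s,S,c,C,n,N]	quaternary nitrogen 1
[s,S,c,C,n,N,o,O]~[n+,N+](~[s,S,c,C,n,N,o,O])(~[s,S,c,C,n,N,o,O])~[s,S,c,C,n,N,o,O]	quaternary nitrogen 2
[*]=[N+]=[*]	quaternary nitrogen 3
O1CCCCC1OC2CCC3CCCCC3C2	saponine derivative
[Si][F,Cl,Br,I]	silicon halogen
c1ccccc1C=Cc2ccccc2	stilbene
[SX3](=O)[O-,OH]	sulfinic acid
[C,c]S(=O)(=O)O[C,c]	Sulfonic acid 1
S(=O)(=O)[O-,OH]	Sulfonic acid 2
S(=O)(=O)C#N	sulfonyl cyanide
[SX2]O	sulfur oxygen single bond
OS(=O)(=O)[O-]	sulphate
[SX2H0][N]	Sulphur-nitrogen single bond
c12ccccc1(SC(S)=N2)	Thiobenzothiazole
c12ccccc1(SC(=S)N2)	thiobenzothiazole
[C,c]=S	Thiocarbonyl group
SC=O	thioester
[S-]	thiol 1
[SH]	thiol 2
*1[O,S,N]*1	Three-membered heterocycle
OS(=O)(=O)C(F)(F)F	triflate
[SiR0,CR0](c1ccccc1)(c2ccccc2)(c3ccccc3)	triphenyl methylsilyl
C#C	triple bond
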