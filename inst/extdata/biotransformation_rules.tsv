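rule_id	smarts	description
bt001	[CX4;H2,H3][OX2H]	primary alcohol - oxidation to aldehyde/acid
bt002	[CX4;H1]([#6])([#6])[OX2H]	secondary alcohol - oxidation to ketone
bt003	c[OX2H]	phenol - ring hydroxylation / conjugation
bt004	c1ccccc1	benzene ring - aromatic monooxygenation
bt005	[CX3](=O)[OX2H1]	carboxylic acid - CoA activation / beta-oxidation entry
bt006	[CX4;H2][CX4;H2][CX3](=O)[OX2H1]	acid with beta-CH2 - beta-oxidation
bt007	[CX3](=O)[OX2][#6]	ester - hydrolysis
bt008	[CX3](=O)[NX3]	amide - hydrolysis
bt009	[CX4][NX3;H2]	primary amine - oxidative deamination
bt010	[NX3;H1]([CX4])[CX4]	secondary amine - N-dealkylation
bt011	[NX3]([CX4])([CX4])[CX4]	tertiary amine - N-dealkylation
bt012	[NX3][CH3]	N-methyl - demethylation
bt013	[OX2]([#6])[CH3]	methyl ether - O-demethylation
bt014	[CX4][OX2][CX4]	dialkyl ether - ether cleavage
bt015	c[OX2][CX4]	aryl alkyl ether - O-dealkylation
bt016	[$([NX3](=O)=O),$([NX3+](=O)[O-])]	nitro group - reduction to amine
bt017	[CX2]#[NX1]	nitrile - hydratase/hydrolysis to amide/acid
bt018	[CX3H1]=O	aldehyde - dehydrogenation to acid
bt019	[#6][CX3](=O)[#6]	ketone - reduction / Baeyer-Villiger oxidation
bt020	[#16X2]([#6])[#6]	thioether - S-oxidation to sulfoxide
bt021	[#16X3]=[OX1]	sulfoxide - further oxidation to sulfone
bt022	[SX4](=O)(=O)[NX3]	sulfonamide - hydrolysis
bt023	[SX4](=O)(=O)[OX2H,OX1-]	sulfonic acid - desulfonation
bt024	[OX2][SX4](=O)(=O)[OX2]	sulfate ester - sulfatase hydrolysis
bt025	[OX2][PX4](=O)	phosphate ester - phosphatase hydrolysis
bt026	[PX4](=S)	thiophosphate - oxidative desulfuration
bt027	c[F,Cl,Br,I]	aryl halide - reductive/hydrolytic dehalogenation
bt028	[CX4][F,Cl,Br,I]	alkyl halide - hydrolytic dehalogenation
bt029	[CX4]([F,Cl,Br,I])([F,Cl,Br,I])[F,Cl,Br,I]	trihalomethyl - recalcitrance marker
bt030	C1OC1	epoxide - epoxide hydrolase
bt031	[OX2][CX3](=O)[NX3]	carbamate - hydrolysis
bt032	[NX3][CX3](=O)[NX3]	urea derivative - hydrolysis
bt033	[NX3][CX3](=[NX2,NX3+])[NX3]	guanidine - hydrolysis (slow)
bt034	c[NX3;H2,H1]	aromatic amine - oxidation / acetylation
bt035	[#6]N=N[#6]	azo group - reductive cleavage
bt036	[CX3H2]=[CX3H1]	terminal alkene - epoxidation/hydration
bt037	[CX3H1]=[CX3H1]	internal alkene - hydration
bt038	C#C	alkyne - oxidation
bt039	c[CX4;H2,H3]	benzylic carbon - hydroxylation
bt040	[CH3][CH2][CH2][CH2]	alkyl chain - omega/subterminal oxidation
bt041	c1cncn1	imidazole ring - recalcitrance marker
bt042	n1ccccc1	pyridine ring - ring cleavage (slow)
bt043	c1ncncn1	triazine ring - hydrolytic dealkylation
bt044	c1ccoc1	furan ring - ring oxidation
bt045	c1ccsc1	thiophene ring - S-oxidation
bt046	[NX4+]	quaternary ammonium - slow N-dealkylation
bt047	[NX3][OX2H]	hydroxylamine - reduction
bt048	[CX3]=[NX2][OX2H]	oxime - hydrolysis
bt049	[NX3][NX3]	hydrazine/hydrazide - cleavage
bt050	[CX4]([OX2][#6])[OX2][#6]	acetal - hydrolysis
bt051	[CX3](=O)[OX2][CX3](=O)	anhydride - spontaneous hydrolysis
bt052	[CX3](=O)[SX2]	thioester - hydrolysis
bt053	[#16X2H]	thiol - oxidation to disulfide
bt054	[OX2][$([NX3](=O)=O),$([NX3+](=O)[O-])]	nitrate ester - reduction
bt055	c[CX3](=O)[OX2H1]	aromatic carboxylic acid - activation
bt056	c[$([NX3](=O)=O),$([NX3+](=O)[O-])]	aromatic nitro - reduction
bt057	[CX4](F)(F)F	trifluoromethyl - recalcitrance marker
bt058	C1COCCN1	morpholine ring - ring cleavage
bt059	C1CNCCN1	piperazine ring - N-dealkylation
bt060	[CX3](=O)[NX3][CH3]	N-methyl amide - demethylation
bt061	c1ccc2ccccc2c1	fused bicyclic aromatic - dioxygenation
bt062	[CX3](=O)[NX3;H2]	primary amide - hydrolysis
bt063	Oc1ccccc1O	catechol - ring cleavage
bt064	[OX2H][CX4][CX4][OX2H]	vicinal diol - oxidation
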