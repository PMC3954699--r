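# version: v1
group	name	rule	params
AtomName	C	indicator	
AtomName	N	indicator	
AtomName	O	indicator	
AtomName	S	indicator	
AtomName	ANY	indicator	
AtomName	OTHER	indicator	
ChemicalGroup	Hydroxyl	indicator	
ChemicalGroup	Amide	indicator	
ChemicalGroup	Amine	indicator	
ChemicalGroup	Carbonyl	indicator	
ChemicalGroup	RingSystem	indicator	
ChemicalGroup	Peptide	indicator	
AtomProperties	VDWVolume	scalar	
AtomProperties	Charge	scalar	
AtomProperties	Hydrophobicity	scalar	
AtomProperties	Mobility	scalar	
AtomProperties	SolventAccessibility	scalar	
AtomProperties	VDWVolume_C	scalar	element=C
AtomProperties	VDWVolume_N	scalar	element=N
AtomProperties	VDWVolume_O	scalar	element=O
AtomProperties	VDWVolume_S	scalar	element=S
AtomProperties	VDWVolume_OTHER	scalar	element=OTHER
AtomProperties	Charge_C	scalar	element=C
AtomProperties	Charge_N	scalar	element=N
AtomProperties	Charge_O	scalar	element=O
AtomProperties	Charge_S	scalar	element=S
AtomProperties	Charge_OTHER	scalar	element=OTHER
AtomProperties	Hydrophobicity_C	scalar	element=C
AtomProperties	Hydrophobicity_N	scalar	element=N
AtomProperties	Hydrophobicity_O	scalar	element=O
AtomProperties	Hydrophobicity_S	scalar	element=S
AtomProperties	Hydrophobicity_OTHER	scalar	element=OTHER
AtomProperties	Mobility_C	scalar	element=C
AtomProperties	Mobility_N	scalar	element=N
AtomProperties	Mobility_O	scalar	element=O
AtomProperties	Mobility_S	scalar	element=S
AtomProperties	Mobility_OTHER	scalar	element=OTHER
AtomProperties	SolventAccessibility_C	scalar	element=C
AtomProperties	SolventAccessibility_N	scalar	element=N
AtomProperties	SolventAccessibility_O	scalar	element=O
AtomProperties	SolventAccessibility_S	scalar	element=S
AtomProperties	SolventAccessibility_OTHER	scalar	element=OTHER
ResidueName	ALA	indicator	
ResidueName	ARG	indicator	
ResidueName	ASN	indicator	
ResidueName	ASP	indicator	
ResidueName	CYS	indicator	
ResidueName	GLN	indicator	
ResidueName	GLU	indicator	
ResidueName	GLY	indicator	
ResidueName	HIS	indicator	
ResidueName	ILE	indicator	
ResidueName	LEU	indicator	
ResidueName	THR	indicator	
ResidueName	LYS	indicator	
ResidueName	MET	indicator	
ResidueName	PHE	indicator	
ResidueName	PRO	indicator	
ResidueName	SER	indicator	
ResidueName	TRP	indicator	
ResidueName	TYR	indicator	
ResidueName	VAL	indicator	
ResidueName	HOH	indicator	
ResidueName	OTHER	indicator	
ResidueProperties	Hydrophobic	indicator	
ResidueProperties	Charged	indicator	
ResidueProperties	Polar	indicator	
ResidueProperties	NonPolar	indicator	
ResidueProperties	Basic	indicator	
ResidueProperties	Acidic	indicator	
SecondaryStructure	3Helix	indicator	
SecondaryStructure	4Helix	indicator	
SecondaryStructure	5Helix	indicator	
SecondaryStructure	Bridge	indicator	
SecondaryStructure	Strand	indicator	
SecondaryStructure	Turn	indicator	
SecondaryStructure	Bend	indicator	
SecondaryStructure	Coil	indicator	
SecondaryStructure	Het	indicator	
SecondaryStructure	Unknown	indicator	
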