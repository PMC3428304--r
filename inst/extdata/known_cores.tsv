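# Piricyclamide core sequences characterized in Microcystis strain
# collections. detected: Z = product observed by LC-MS, X = precursor gene
# only. mods: G = geranyl, P = prenyl, SS = disulfide bridge (in addition to
# head-to-tail macrocyclization).
core	detected	mods	strains
NEFMQTGSYSGP	Z	G	PCC7005
TFCDLATKQCYP	Z	SS	PCC7005,SYKE864,NIES843
WILLADGTRPKNAP	Z		PCC7005
MSGVDYYNP	Z	G	PCC7005
TLGCMNGTERCLGLP	Z	SS	Izancya36,Izancya41
DWGTFCVQEDGEGNCKEWYEVP	X		Izancya36,Izancya41
DWGTFCVQEDGEGNCKGWYELP	X		SYKE864,NIES843
GTHLYTITP	Z	P	SYKE864
APLWDLVRWGAP	X		NIES843
ILGEGEGWNYNP	Z	P	Izancya42,SYKE764
FAIFLLLP	Z		Izancya42
YSNVLPP	X		Izancya42
SQWGWRGLSDP	Z		SYKE764
GWGTFCVGEDGDGNCEEWYELP	X		SYKE764
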