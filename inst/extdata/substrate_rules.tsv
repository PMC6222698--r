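rule_id	subgroup	arr	froger	lb_box	le_box	hove	azad	provenance
PIP1_default	PIP1	F,H,T,R	Q,S,A,F,W	*	*	Boron,CO2,H2O2,Urea	CO2,H2O2	Hove2011;Azad2016
PIP2_MSAFW	PIP2	F,H,T,R	M,S,A,F,W	*	*	Ammonia,Urea	Ammonia	Hove2011;Azad2016
PIP2_QSAFW_LEF	PIP2	F,H,T,R	Q,S,A,F,W	*	GTGINPARSFG	H2O2,Urea	H2O2	Hove2011;Azad2016
PIP2_QSAFW_LEL	PIP2	F,H,T,R	Q,S,A,F,W	*	GTGINPARSLG	Boron,CO2,H2O2,Urea	CO2	Hove2011;Azad2016
TIP1_AIT	TIP1	H,I,A,V	T,S,A,Y,W	SGGHVNPAIT	*			Hove2011;Azad2016
TIP1_TTAYW	TIP1	H,I,A,V	T,T,A,Y,W	*	*	Urea		Hove2011
TIP1_AVT	TIP1	H,I,A,V	T,S,A,Y,W	SGGHVNPAVT	*	H2O2,Urea	H2O2,Urea	Hove2011;Azad2016
TIP2_default	TIP2	H,I,G,R	T,S,A,Y,W	*	*	H2O2,Urea	H2O2,Urea	Hove2011;Azad2016
TIP3_default	TIP3	H,I,A,R	T,A,A,Y,W	*	*	H2O2,Urea		Hove2011
TIP4_default	TIP4	H,I,A,R	T,S,A,Y,W	*	*			none
TIP5_default	TIP5	N,V,G,Y	T,S,A,Y,W	*	*			none
NIP4_default	NIP4	W,F,A,R	F,S,A,Y,I	*	*			none
NIP5_default	NIP5	A,I,G,R	F,T,A,Y,L	*	*	Boron	Boron	Hove2011;Azad2016
NIP6_AIAR	NIP6	A,I,A,R	F,T,A,Y,L	*	*	Boron		Hove2011
NIP6_SIGR	NIP6	S,I,G,R	Y,T,A,Y,I	*	*			none
NIP6_SIAR	NIP6	S,I,A,R	Y,T,A,Y,M	*	*			none
SIP1_default	SIP1	I,V,P,N	M,A,A,Y,W	*	*			none
SIP2_SQGS	SIP2	S,Q,G,S	F,V,A,Y,W	*	*			none
SIP2_SHGS	SIP2	S,H,G,S	F,V,A,Y,W	*	*			none
XIP1_default	XIP1	I,T,A,R	V,C,A,Y,W	*	*			none
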