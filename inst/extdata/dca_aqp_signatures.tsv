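gene	subgroup	lb_box	le_box	arr	froger	hove	azad
DcaPIP1;1	PIP1	SGGHINPAVT	GTGINPARSLG	F,H,T,R	Q,S,A,F,W	Boron,CO2,H2O2,Urea	CO2,H2O2
DcaPIP1;2	PIP1	SGGHINPAVT	GTGINPARSLG	F,H,T,R	Q,S,A,F,W	Boron,CO2,H2O2,Urea	CO2,H2O2
DcaPIP1;3	PIP1	SGGHINPAVT	GTGINPARSLG	F,H,T,R	Q,S,A,F,W	Boron,CO2,H2O2,Urea	CO2,H2O2
DcaPIP2;1	PIP2	SGGHINPAVT	GTGINPARSFG	F,H,T,R	M,S,A,F,W	Ammonia,Urea	Ammonia
DcaPIP2;2	PIP2	SGGHINPAVT	GTGINPARSFG	F,H,T,R	M,S,A,F,W	Ammonia,Urea	Ammonia
DcaPIP2;3	PIP2	SGGHINPAVT	GTGINPARSFG	F,H,T,R	Q,S,A,F,W	H2O2,Urea	H2O2
DcaPIP2;4	PIP2	SGGHINPAVT	GTGINPARSFG	F,H,T,R	Q,S,A,F,W	H2O2,Urea	H2O2
DcaPIP2;5	PIP2	SGGHINPAVT	GTGINPARSFG	F,H,T,R	Q,S,A,F,W	H2O2,Urea	H2O2
DcaPIP2;6	PIP2	SGGHINPAVT	GTGINPARSLG	F,H,T,R	Q,S,A,F,W	Boron,CO2,H2O2,Urea	CO2
DcaTIP1;1	TIP1	SGGHVNPAIT	GASMNPAVSFG	H,I,A,V	T,S,A,Y,W		
DcaTIP1;2	TIP1	SGGHVNPAVT	GASMNPAVTFG	H,I,A,V	T,T,A,Y,W	Urea	
DcaTIP1;3	TIP1	SGGHVNPAIT	GASMNPAVSFG	H,I,A,V	T,S,A,Y,W		
DcaTIP1;4	TIP1	SGGHVNPAVT	GASMNPAVSFG	H,I,A,V	T,S,A,Y,W	H2O2,Urea	H2O2,Urea
DcaTIP2;1	TIP2	SGGHLNPAVT	GGSMNPARSFG	H,I,G,R	T,S,A,Y,W	H2O2,Urea	H2O2,Urea
DcaTIP2;2	TIP2	SGGHVNPAVT	GGSMNPARSFG	H,I,G,R	T,S,A,Y,W	H2O2,Urea	H2O2,Urea
DcaTIP3;1	TIP3	SGGHVNPAVT	GASMNPARAFG	H,I,A,R	T,A,A,Y,W	H2O2,Urea	
DcaTIP3;2	TIP3	SGGHVNPAVT	GASMNPARAFG	H,I,A,R	T,A,A,Y,W	H2O2,Urea	
DcaTIP3;3	TIP3	SGGHVNPAVT	GASMNPARAFG	H,I,A,R	T,A,A,Y,W	H2O2,Urea	
DcaTIP4;1	TIP4	SGGHLNPAVT	AASMNPARSFG	H,I,A,R	T,S,A,Y,W		
DcaTIP5;1	TIP5	SGGHVNPAVT	GGSMNPAYSFG	N,V,G,Y	T,S,A,Y,W		
DcaNIP4;1	NIP4	SGAHFNPAVT	GASMNPARSIG	W,F,A,R	F,S,A,Y,I		
DcaNIP5;1	NIP5	SGAHLNPSLT	GGSMNPVRTLG	A,I,G,R	F,T,A,Y,L	Boron	Boron
DcaNIP5;2	NIP5	SGAHLNPSLT	GGSMNPVRTLG	A,I,G,R	F,T,A,Y,L	Boron	Boron
DcaNIP6;1	NIP6	SGAHLNPALT	GASMNPVRTLG	A,I,A,R	F,T,A,Y,L	Boron	
DcaNIP6;2	NIP6	SGAHINLAVS	GGSMNPARTVG	S,I,G,R	Y,T,A,Y,I		
DcaNIP6;3	NIP6	SKAHFNPAVT	GASMNPARTLG	S,I,A,R	Y,T,A,Y,M		
DcaSIP1;1	SIP1	GGASFNPTGT	GFSMNPANAFG	I,V,P,N	M,A,A,Y,W		
DcaSIP2;1	SIP2	KAGNYNPLTL	GGCMNPASVMG	S,Q,G,S	F,V,A,Y,W		
DcaSIP2;2	SIP2	NGAAYNPLTV	GGCMNPASVMG	S,H,G,S	F,V,A,Y,W		
DcaXIP1;1	XIP1	SGGHINPSVT	GAGMNPARCVG	I,T,A,R	V,C,A,Y,W		
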