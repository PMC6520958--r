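enzyme	ec	kind	p4	p3	p2	p1	p1p	p2p	p3p	p4p
trypsin	3.4.21.4	cleave	.	.	.	KR	.	.	.	.
trypsin	3.4.21.4	block	.	.	^W	K	P	.	.	.
trypsin	3.4.21.4	block	.	.	^M	R	P	.	.	.
trypsin	3.4.21.4	block	.	.	CD	K	D	.	.	.
trypsin	3.4.21.4	block	.	.	C	K	HY	.	.	.
trypsin	3.4.21.4	block	.	.	C	R	K	.	.	.
trypsin	3.4.21.4	block	.	.	R	R	HR	.	.	.
chymotrypsin_low	3.4.21.1	cleave	.	.	.	FYWLMH	^P	.	.	.
chymotrypsin_low	3.4.21.1	block	.	.	.	W	M	.	.	.
chymotrypsin_low	3.4.21.1	block	.	.	.	M	Y	.	.	.
chymotrypsin_low	3.4.21.1	block	.	.	.	H	DMW	.	.	.
pepsin_ph1.3	3.4.23.1	cleave	.	^HKR	^P	FL	.	.	.	.
pepsin_ph1.3	3.4.23.1	cleave	.	^HKR	^P	.	FL	^P	.	.
pepsin_ph2	3.4.23.1	cleave	.	^HKR	^P	FLWY	.	.	.	.
pepsin_ph2	3.4.23.1	cleave	.	^HKR	^P	.	FLWY	^P	.	.
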