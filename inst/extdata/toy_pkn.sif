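Akt	-1	MEK
IKK	1	NFkB
MAP3K1	1	IKK
MAP3K1	1	MKK4
MAP3K1	1	p38
MEK	1	ERK
MKK4	1	JNK
p38	1	Hsp27
PI3K	1	Akt
PI3K	1	MKK4
RAS	1	MEK
TGFa	1	PI3K
TGFa	1	RAS
TNFa	1	TRAF2
TRAF2	1	MAP3K1
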