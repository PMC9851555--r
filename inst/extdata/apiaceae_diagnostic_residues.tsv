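sequence	name	p106	p115	p116	p131	p195	p200	p215	p216	class
DCAR_009489	DcFNS I	T	T	I	F	E	I	V	R	FNS_I
DCAR_009487	DcFNS I-like	P	I	V	F	E	I	C	R	FNS_I_LIKE
DCAR_009488	DcFNS I-like	T	T	V	F	E	I	V	R	FNS_I_LIKE
DCAR_009483	DcF3H	M	I	V	I	D	V	L	K	F3H
CM020904_g37715	AgFNS I-like	T	T	I	F	K	I	C	R	FNS_I_LIKE
CM020901_g36861	AgFNS I	T	T	I	F	E	I	V	R	FNS_I
CM020901_g36676	AgF3H	M	I	V	I	D	V	L	K	F3H
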