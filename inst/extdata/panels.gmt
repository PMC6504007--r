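pluripotency	core pluripotency network genes	KLF17	MYC	NANOG	KLF4	MBD3	SOX2	BMP4	POU5F1
kmt	H3K4/H3K9/H3K27 lysine methyltransferases	KMT2A	KMT2C	KMT2E	SUV39H1	SUV39H2	SETDB1	SETDB2	PRDM2	EZH1	EZH2
kdm	H3K4/H3K9/H3K27 lysine demethylases	KDM4A	KDM4B	KDM4C	KDM4D	KDM5A	KDM5B	KDM5C	KDM5D	KDM6A	KDM6B
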