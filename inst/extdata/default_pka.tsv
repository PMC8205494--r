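group	polarity	pka
D	acid	3.9
E	acid	4.25
H	base	6.5
C	acid	8.5
Y	acid	10.46
K	base	10.53
R	base	12.48
nterm	base	8
cterm	acid	3.6
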