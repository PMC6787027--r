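variant_id	heptamer	p_anticodon_3to5	a_anticodon_3to5	fs	sigma
A1 AAA4 AAG7 / Lys-Lys	AAAAAAG	UUS	UUS	0.80	0.02
G1 AAA4 AAG7 / Lys-Lys	GAAAAAG	UUS	UUS	0.28	0.02
A1 AAG4 AAG7 / Lys-Lys	AAAGAAG	UUS	UUS	0.44	0.02
A1 AAA4 AAA7 / Lys-Lys	AAAAAAA	UUS	UUS	0.50	0.02
U1 UUU4 UUU7 / Phe-Phe	UUUUUUU	AAG	AAG	0.50	0.02
G1 AAG4 AAG7 / Lys-Lys	GAAGAAG	UUS	UUS	0.08	0.02
C1 AAG4 AAG7 / Lys-Lys	CAAGAAG	UUS	UUS	0.09	0.02
C1 AAG4 AAA7 / Lys-Lys	CAAGAAA	UUS	UUS	0.02	0.02
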