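name	iupac
SuH	YGTGRGAA
Abox	RCAGSTG
Brd	AGCTTTA
GY	GTCTTCC
K	TGTGAT
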