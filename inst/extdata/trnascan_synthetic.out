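Sequence		tRNA	Bounds	tRNA	Anti	Intron Bounds	Inf
Name    	tRNA #	Begin	End	Type	Codon	Begin	End	Score	Note
--------	------	-----	----	----	-----	-----	----	------	----
chrS	1	11	82	Phe	GAA	0	0	81.5
chrS	2	101	184	Tyr	GTA	138	151	74.2
chrS	3	290	219	Ala	AGC	0	0	68.0
chrS	4	301	372	Ala	AGC	0	0	62.3	pseudo
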