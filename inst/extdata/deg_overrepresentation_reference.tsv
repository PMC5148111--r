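term	category	name	ref	count	expected	fold_printed
GO:0008152	BP	metabolic process	6594	460	350.07	1.31
GO:0044238	BP	primary metabolic process	5592	385	296.87	1.30
GO:0009056	BP	catabolic process	836	74	44.38	1.67
GO:0019538	BP	protein metabolic process	2001	146	106.23	1.37
GO:0006807	BP	nitrogen compound metabolic process	1982	151	105.22	1.44
GO:0040011	BP	locomotion	153	21	8.12	2.59
GO:0006397	BP	mRNA processing	241	28	12.79	2.19
GO:0003824	MF	catalytic activity	5114	376	271.5	1.38
GO:0008009	MF	chemokine activity	46	12	2.44	4.91
GO:0005515	MF	protein binding	2719	191	144.35	1.32
GO:0016787	MF	hydrolase activity	2175	153	115.47	1.33
P06959	pathway	CCKR signaling map	169	26	8.97	2.90
P00005	pathway	Angiogenesis	168	22	8.92	2.47
P00057	pathway	Wnt signaling pathway	278	30	14.76	2.03
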