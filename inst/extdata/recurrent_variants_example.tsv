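sample	chr	position	ref	alt	allele_fraction	gene	consequence	cadd_phred	gnomad_freq
PN14	chr20	57484420	C	T	41.7%	GNAS	Missense variant	34	0
PN13	chr20	57484420	C	T	41.0%	GNAS	Missense variant	34	0
PN08	chr20	57484420	C	T	45.4%	GNAS	Missense variant	34	0
PN01	chr16	31818244	C	G	10.3%	AC002519.6	Downstream gene variant	2.24	0
PN07	chr16	31818244	C	G	16.7%	AC002519.6	Downstream gene variant	2.24	0
PN02	chr11	62283636	T	C		AHNAK	3 prime UTR variant	0.57	0
PN01	chr11	62289022	T	A		AHNAK	Synonymous variant	0.008	0.003%
PN06	chr9	112625173	G	T		PALM2/AKAP2	Intron variant	1.26	0
PN15	chr9	112687347	T	A		PALM2/AKAP2	Missense variant	19.12	0
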