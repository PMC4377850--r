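type	library	total_count	total_percent	unique_count	unique_percent	unique_percent_denominator
Raw reads	NT	9919778	100.00	2280543	100.00	unique
3ADT&length filter	NT	1432000	14.44	333989	14.65	unique
Junk reads	NT	27989	0.28	14986	0.66	unique
Rfam	NT	1181057	11.91	118282	5.19	unique
mRNA	NT	4132	0.04	2480	0.11	unique
Repeats	NT	63383	0.64	20334	0.89	unique
rRNA	NT	860830	8.68	72264	0.73	total
tRNA	NT	197083	1.99	19182	0.19	total
snoRNA	NT	17886	0.18	5419	0.05	total
snRNA	NT	15389	0.16	5618	0.06	total
other Rfam RNA	NT	89869	0.91	15799	0.16	total
Clean reads	NT	7231609	72.90	1795513	78.73	unique
Raw reads	CT	6199678	100.00	1521423	100.00	unique
3ADT&length filter	CT	1009234	16.28	196123	12.89	unique
Junk reads	CT	14948	0.24	8225	0.54	unique
Rfam	CT	795804	12.84	95041	6.25	unique
mRNA	CT	3320	0.05	2007	0.13	unique
Repeats	CT	50626	0.82	16844	1.11	unique
rRNA	CT	524172	8.45	53070	0.86	total
tRNA	CT	184888	2.98	19919	0.32	total
snoRNA	CT	17466	0.28	4893	0.08	total
snRNA	CT	12882	0.21	4598	0.07	total
other Rfam RNA	CT	56396	0.91	12561	0.20	total
Clean reads	CT	4342604	70.05	1208259	79.42	unique
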