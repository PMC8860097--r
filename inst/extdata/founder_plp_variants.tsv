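# Published table of BRCA founder PLP variants whose arisen times were dated
# by haplotype analysis in the original population studies; one row per
# founder record (the same variant in two populations is two records).
# Ages are literature inputs and are never recomputed here. Printed age
# ranges "old-young" are split into age_bp (older bound) and age_bp_min;
# the "<200" entry is stored as age_bp 200 with an empty age_bp_min.
# Mutation names keep the published cDNA (HGVS where printed); legacy
# mutation aliases are in the legacy_name column. Empty cells stay empty.
gene	age_bp	age_bp_min	population	hgvs_c	legacy_name	hgvs_p	type
BRCA1	3225		Tuscany, Italy	c.3228_3229del	3347delAG	p.G1077fs	frameshift
BRCA1	2400	1600	Iberia	c.3331_3334delCAAG		p.Q1064fs	frameshift
BRCA1	1800		Ashkenazi Jewish	c.5266dupC	5832insC	p.Q1756fs	frameshift
BRCA1	1720		Northeastern Italy	c.676delT		p.C226fs	frameshift
BRCA1	1500	750	Ashkenazi Jewish	c.68_69del	185delAG	p.E23fs	frameshift
BRCA1	1500		Swedish	c.3052_3053ins5	3171ins5
BRCA1	1480		Columbia	c.3331_3334del	3450delCAAG	p.Q1064fs	frameshift
BRCA1	1440		Mexican	c.548-?_4185+?del			exon 9-12del
BRCA1	800		Moroccan	c.5309G>T		p.G1770V	missense
BRCA1	750		Tuscany, Italy	c.1380dup	1499insA	p.F414fs	frameshift
BRCA1	720	460	Finnish	c.3626del	3744delT		nonsense
BRCA1	600		Norwegians	c.1556del	1675delA	p.K472fs	frameshift
BRCA1	600		Norwegians	c.1135_1136insA	1135insA	p.K472fs	frameshift
BRCA1	500		Norwegians	c.697_698del	816delGT	p.V186fs	frameshift
BRCA1	500		Norwegians	c.3228_3229del	3347delAG	p.G1077fs	frameshift
BRCA1	500		South Africans	c.2641G>T		p.E881X	nonsense
BRCA1	380		Spanish	c.5153-1G>A			splice site
BRCA1	275		Greek	c.5212G>A	G1738R	p.G1738R	missense
BRCA1	200		Dutch	c.2685_2686del	2804delAA	p.P850fs	frameshift
BRCA1	200		Afro-Americans	c.824_825ins10	943ins10
BRCA1	200		Finnish	c.4097-2A>G	4216-2A>G		splice site
BRCA1	180		Unknown	c.1175_1214del	1294del40	p.L345fs	frameshift
BRCA2	2760		Spanish	c.9026_9030del	9254del5	p.T3009fs	frameshift
BRCA2	2600	2400	Portugal	c.1205T>C	156-157insAlu	p.L402P	missense
BRCA2	1904		Spanish	c.5116_5119del	5344delAATA	p.N1706fs	frameshift
BRCA2	1600		US and Canda	c.3036_3039del		p.S1013fs	frameshift
BRCA2	1365		Spanish	c.9310_9311delAA	9538delAA	p.L3104fs	frameshift
BRCA2	1200		Spanish	c.5146_5149del	5374delTATG	p.T1716fs	frameshift
BRCA2	580		Ashkenazi Jewish	c.5946del	6174delT	p.S1982fs	frameshift
BRCA2	500		Icelaner	c.771_775del	995del5	p.A257fs	frameshift
BRCA2	400	200	Finnish	c.7480C>T	7708C>T	p.R2494X	nonsense
BRCA2	360		US and France	c.755_758del	982del4	p.D252fs	frameshift
BRCA2	220	140	Finnish	c.8327T>G	8555T>G	p.L2776X	nonsense
BRCA2	220	140	Finnish	c.9118-2A>G			splice site
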