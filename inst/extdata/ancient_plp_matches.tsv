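# Published table of BRCA PLP variants detected in ancient-human genome
# sequences (one row per individual-variant detection record), transcribed
# verbatim. age_bp/age_sd split the printed "age +/- sd"; point estimates
# without an uncertainty leave age_sd empty; empty domain cells stay empty.
# Type labels are verbatim (the table mixes "stopgain"/"nonsense" and
# "missense"/"nonsynonymous"; summaries count verbatim labels and report a
# merged stopgain-like class alongside).
gene	age_bp	age_sd	site	hgvs_c	hgvs_p	type	rsid	domain
BRCA1	37470	1210	Voronezh Oblast, Russia	c.181T>G	p.C61G	missense	rs28897672	Zinc finger
BRCA1	9871	1650	Bor District, Serbia	c.5095C>T	p.R1699W	missense	rs55770810	BRCT
BRCA1	7796.5	75.5	Shandong, China	c.2059C>T	p.Q687X	stopgain	rs273898674
BRCA1	4971	450	Catalonia, Spain	c.1A>G	p.D2_M18del	startloss	rs80357287
BRCA1	4671	50	Sistan and Baluchestan, Iran	c.4327C>T	p.R1443X	stopgain	rs41293455
BRCA1	4121	100	Senec, Slovakia	c.3607C>T	p.R1203X	stopgain	rs62625308
BRCA1	3350	200	Sardinia, Italy	c.1618G>T	p.E540X	stopgain	rs730881471
BRCA1	3096	20	Hope Town, Bahamas	c.5503C>T	p.R1835X	stopgain	rs41293465	BRCT
BRCA1	2110	30	Ballito Bay, South Africa	c.643C>T	p.Q215X	stopgain	rs886037979
BRCA1	2110	30	Ballito Bay, South Africa	c.949C>T	p.Q317X	stopgain	rs80357211
BRCA1	2110	30	Ballito Bay, South Africa	c.441+1G>A		splice site	rs397509172
BRCA1	2031		Khovsgol, Mongolia	c.135-1G>A		splice site	rs80358158
BRCA1	1980	20	Ballito Bay, South Africa	c.3967C>T	p.Q1323X	stopgain	rs80357262
BRCA1	1933		Rostov Oblast, Russia	c.5353C>T	p.Q1785X	nonsense	rs80356969	BRCT
BRCA1	1695	195	Chukotka, Russia	c.2761C>T	p.Q921X	nonsense	rs80357377
BRCA1	1471	50	Girona, Catalonia	c.4255G>T	p.E1419X	stopgain	rs80357309
BRCA1	1221	100	Monsenor Nouel, Dominica	c.2309C>A	p.S770X	stopgain	rs80357063
BRCA1	921	500	Monsenor Nouel, Dominica	c.3607C>T	p.R1203X	stopgain	rs62625308
BRCA1	921	500	Monsenor Nouel, Dominica	c.5096G>A	p.R1699Q	missense	rs41293459	BRCT
BRCA1	921	500	Monsenor Nouel, Dominica	c.4327C>T	p.R1443X	stopgain	rs41293455
BRCA1	921	500	Monsenor Nouel, Dominica	c.5216A>T	p.D1739V	missense	rs80357227	BRCT
BRCA1	921	500	Monsenor Nouel, Dominica	c.5095C>T	p.R1699W	missense	rs55770810	BRCT
BRCA1	721	100	San Pedro de Macors, Dominica	c.2389G>T	p.E797X	stopgain	rs62625306
BRCA1	721	100	San Pedro de Macors, Dominica	c.5503C>T	p.R1835X	stopgain	rs41293465	BRCT
BRCA1	480	30	Eland Cave, South Africa	c.5074G>A	p.D1692N	nonsynonymous	rs80187739	BRCT
BRCA1	480	30	Eland Cave, South Africa	c.3403C>T	p.Q1135X	stopgain	rs80357136
BRCA1	419	94	Guangxi, China	c.4573C>T	p.Q1525X	stopgain	rs886040237	SRD
BRCA1	307.5	26.5	Fujian, China	c.2599C>T	p.Q867X	stopgain	rs886038001
BRCA2	7874	72	Bor District, Serbia	c.9573G>A	p.W3191X	stopgain	rs398122617	NAB
BRCA2	7030	50	Castile and Leon, Spain	c.9466C>T	p.Q3156X	stopgain	rs276174925	NAB
BRCA2	4950	150	Baden, Germany	c.6952C>T	p.R2318X	stopgain	rs80358920
BRCA2	4571	350	Kladno, Central Bohemian Region	c.9382C>T	p.R3128X	stopgain	rs80359212
BRCA2	4384	200	Scotland, UK	c.3922G>T	p.E1308X	stopgain	rs80358638
BRCA2	4250	1200	Vrancea County, Romania	c.7806-2A>G		splicing	rs81002836
BRCA2	3858	200	Budapest, Hungary	c.8695C>T	p.Q2899X	stopgain	rs397507411
BRCA2	3546	325	Atyrau region, Kazakhstan	c.244A>T	p.K82X	stopgain	rs397507628
BRCA2	2921	100	NWFP, Pakistan	c.1189C>T	p.Q397X	stopgain	rs760815829
BRCA2	2921	100	NWFP, Pakistan	c.3469G>T	p.E1157X	stopgain	rs80358595
BRCA2	2821	100	East Kazakhstan, Kazakhstan	c.1825C>T	p.Q609X	stopgain	rs80358472
BRCA2	2821	100	East Kazakhstan, Kazakhstan	c.2455C>T	p.Q819X	stopgain	rs397507629
BRCA2	2330	25	St. Helena, South Africa	c.2905C>T	p.Q969X	stopgain	rs886038080
BRCA2	2321	100	NWFP, Pakistan	c.5200G>T	p.E1734X	stopgain	rs786202543
BRCA2	2131		Khovsgol, Mongolia	c.316+1G>A		splice site	rs397507303
BRCA2	2083		Omnogovi, Mongolia	c.7617+1G>A		splice site	rs397507922
BRCA2	1980	20	Ballito Bay, South Africa	c.7480C>T	p.R2494X	stopgain	rs80358972
BRCA2	1783		Issyk Kul, Kyrgyzstan	c.7007G>A	p.R2336H	missense	rs28897743
BRCA2	1697		South Kazakhstan, Kazakhstan	c.7977-1G>A		splice site	rs81002874
BRCA2	1100	500	Santo Domingo, Dominica	c.171C>A	p.Y57X	stopgain	rs201523522
BRCA2	480	30	Eland Cave, South Africa	c.475G>A	p.V159M	nonsynonymous	rs80358702
BRCA2	350	100	Shefa, Vanuatu	c.8009C>T	p.S2670L	missense	rs80359035	NAB
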