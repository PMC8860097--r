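# Published counts of human BRCA1/BRCA2 pathogenic + likely-pathogenic (PLP)
# variants (ClinVar 2020-10 snapshot) and their sharing across 100 vertebrate
# species. Counts transcribed verbatim from the published summary table.
# Section A: the PLP set by significance class and consequence type.
# Section B: variants shared with at least one non-human species, by type.
# Section C: histogram - number of variants shared with exactly k species.
# Verbatim-transcription notes:
#   * the published BRCA2 shared percent prints 8.6 where 312/3652 computes
#     to 8.5; the printed total column of section C prints 65 at k=2 (addends
#     give 64) and 4 at k=19 (addends give 3). Kept verbatim, not "fixed".
#   * "-" cells (type never shared / zero count) are stored as 0.
section	label	brca1	brca2	total
A	total	2972	3652	6624
A	pathogenic	2767	3396	6163
A	likely_pathogenic	110	155	265
A	pathogenic/likely_pathogenic	95	101	196
A	frameshift deletion	1250	1676	2926
A	stopgain/nonsense	655	851	1506
A	frameshift insertion	622	738	1360
A	splice site	176	190	366
A	nonsynonymous SNV	116	47	163
A	frameshift substitution	88	114	202
A	intron variant	48	18	66
A	nonframeshift deletion	10	12	22
A	nonframeshift substitution	6	5	11
A	5'/3' UTR	1	1	2
B	shared_mutation	172	312	484
B	stopgain/nonsense	156	280	436
B	splice site	6	17	23
B	nonsynonymous SNV	5	8	13
B	intron variant	5	7	12
B	frameshift deletion	0	0	0
B	frameshift insertion	0	0	0
B	nonframeshift deletion	0	0	0
B	5'/3' UTR	0	0	0
C	1	68	130	198
C	2	24	40	65
C	3	14	36	50
C	4	7	18	25
C	5	19	15	34
C	6	6	12	18
C	7	8	8	16
C	8	3	5	8
C	9	2	4	6
C	10	2	4	6
C	11	4	1	5
C	12	2	2	4
C	13	1	4	5
C	14	1	3	4
C	15	3	5	8
C	16	2	5	7
C	17	3	2	5
C	18	2	6	8
C	19	1	2	4
C	20	0	4	4
C	21	0	2	2
C	25	0	1	1
C	34	0	1	1
C	36	0	1	1
C	57	0	1	1
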