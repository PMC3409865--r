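# Published per-miRNA read counts (control GP vs transgenic TaDREB3 libraries), the
# transgenic counts normalized by the control/transgenic total-count ratio, and the
# log2(normalized/control) ratio. "#NUM!" marks undefined log2 (a zero count on one side).
# Three published rows merge a mature and its star partner's counts into single fields;
# here mature and star are separate rows, mature counts back-solved from the published
# normalized and log2 columns (exact integers), star rows carry the residual digits and
# have no published normalized/log2 (empty fields). is_star: 1 for star-partner rows.
mirna	sequence	is_star	count_ctrl	count_tg	normalized_tg	log2
hvu-miR5048	UAUUUGCAGGUUUUAGGUCUAA	0	4547	2106	2912.955844	-0.642431171
hvu-miR159a/b	UUUGGAUUGAAGGGAGCUCUG	0	2246	4260	5892.303845	1.391473899
hvu-miR159a*	GAGCTCCTATCATTCCAATGA	1	5	2
hvu-miR444b	UGCAGUUGCUGUCUCAAGCUU	0	64	30	41.4950975	-0.625131008
hvu-miR1120	ACAUUCUUAUAUUAUGGGACGGAG	0	387	94	130.0179722	-1.573622508
hvu-miR444a	UUGCUGCCUCAAGCUUGCUGC	0	1	0	0	#NUM!
hvu-miR156	UGACAGAAGAGAGUGAGCACA	0	140769	213440	295223.787	1.068479308
hvu-miR1436	ACAUUAUGGGACGGAGGGAGU	0	8	2	2.766339833	-1.532021604
hvu-miR5050	UUGAGGUCGUUCAACCAGCAA	0	57	27	37.34558775	-0.610024116
hvu-miR5051	UUUGGCACCUUGAAACUGGGA	0	4	5	6.915849583	0.789906491
hvu-miR5051*	CCAGTTTCAAGGTTTCAAAGC	1	1	0
hvu-miR171	UGAUUGAGCCGUGCCAAUAUC	0	158	88	121.7189527	-0.376370733
hvu-miR168-3p	GAUCCCGCCUUGCACCAAGUG	0	404	293	405.2687856	0.004523768
hvu-miR168-3p*	AAUCCCGCCTTGCACCAAGTGAAT	1	324	248
hvu-miR399	UGCCAAAGGAGAUUUGCCCCG	0	2	1	1.383169917	-0.532021604
hvu-miR5049	UCCUAAAUACUUGUUGUUGGG	0	549	121	167.3635599	-1.713820705
hvu-miR397	CCGUUGAGUGCAGCGUUGAUG	0	8	7	9.682189416	0.275333318
hvu-miR166/b/c	UCGGACCAGGCUUCAUUCCCC	0	19883	6967	9636.544809	-1.044947586
hvu-miR1126	UCAACUAUGGACUACAUACGGAA	0	13	0	0	#NUM!
hvu-miR5052	ACCGGCUGGACGGUAGGCAUA	0	11	3	4.14950975	-1.406490722
hvu-miR168-5p	UCGCUUGGUGCAGAUCGGGAC	0	420777	179792	248682.8857	-0.758748623
hvu-miR5053	CGCAGCUGUAGUCGCCGGCGU	0	24	5	6.915849583	-1.795056009
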