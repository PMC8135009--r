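virus_id	accession	classification	reads_amc_rna	pass_amc_rna	reads_ad_rna	pass_ad_rna	reads_amc_dna	pass_amc_dna	reads_ad_dna	pass_ad_dna	rna_diff_p
HERV_K113	NC_022518.1	ssRNA-RT	1289	TRUE	2242	TRUE	3586	TRUE	4698	TRUE	NA
Human_herpesvirus_1	NC_001806.1	dsDNA	162	FALSE	327	FALSE	192	TRUE	183	TRUE	NA
Human_herpesvirus_2	NC_001798.1	dsDNA	12806	TRUE	28052	TRUE	1403	TRUE	1589	FALSE	0.0001
Human_herpesvirus_4	NC_007605.1	dsDNA	137	FALSE	234	TRUE	200	TRUE	178	TRUE	NA
Human_herpesvirus_6B	NC_000898.1	dsDNA	521	FALSE	1476	TRUE	2411	TRUE	2627	TRUE	0.0001
Human_adenovirus_54	NC_012959.1	dsDNA	273	TRUE	440	TRUE	14	FALSE	10	FALSE	NA
Hepatitis_C_virus_type_2	NC_009823.1	+ssRNA	5492	FALSE	15501	FALSE	19181	TRUE	22028	FALSE	0.0001
Human_papillomavirus_6	HPV6REF.1	dsDNA	82	FALSE	140	FALSE	151	FALSE	218	TRUE	NA
Human_papillomavirus_9	HPV9REF.1	dsDNA	121	FALSE	405	FALSE	94	TRUE	112	FALSE	0.0001
Human_papillomavirus_72	HPV72REF.1	dsDNA	334	TRUE	692	FALSE	22	FALSE	33	FALSE	0.001
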