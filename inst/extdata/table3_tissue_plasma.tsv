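# Matched tumor-tissue / plasma mutation calls for the APC, KRAS and TP53
# genes in a 16-patient colorectal-cancer cohort (targeted 523-gene panel).
# One row per detected mutation; "Negative" table cells contribute no rows.
# vaf_pct is the reported variant (minor) allele frequency in percent.
# Transcribed from the published concordance evaluation this package models.
patient_id	gene	sample_type	hgvs_c	vaf_pct
14	APC	tissue	c.3736_3740del	33.3
14	TP53	tissue	c.637C>T	96.6
14	TP53	plasma	c.637C>T	0.7
29	APC	tissue	c.834G>A	35.9
29	APC	tissue	c.1312+2T>C	42.4
29	APC	plasma	c.834G>A	3.5
29	APC	plasma	c.1312+2T>C	6.3
32	APC	tissue	c.4432_4460del	81.7
32	APC	tissue	c.6614C>G	41.1
32	APC	plasma	c.4432_4460del	1.2
32	KRAS	tissue	c.35G>T	38.5
38	APC	tissue	c.4666dup	83.3
38	KRAS	tissue	c.183A>C	45.6
52	APC	tissue	c.1690C>T	16.3
52	APC	tissue	c.4476del	12.6
52	KRAS	tissue	c.38G>A	24.7
52	KRAS	plasma	c.38G>A	0.4
52	KRAS	plasma	c.404G>C	20
53	APC	tissue	c.646C>T	66.9
53	TP53	tissue	c.1010G>T	64.4
53	TP53	plasma	c.1010G>T	1.1
55	APC	tissue	c.2821G>T	19.4
55	APC	tissue	c.4364del	41.9
55	APC	plasma	c.4364del	4.7
55	KRAS	tissue	c.34G>A	61.9
55	KRAS	plasma	c.34G>A	9.8
59	APC	plasma	c.5463G>T	0.6
59	KRAS	tissue	c.38G>A	11.9
59	KRAS	plasma	c.38G>A	10.9
59	TP53	plasma	c.740A>G	0.5
68	TP53	tissue	c.817C>T	14.1
68	TP53	plasma	c.817C>T	5.9
73	APC	tissue	c.2932C>T	77.7
73	KRAS	tissue	c.35G>A	53.9
73	TP53	tissue	c.586C>T	79.1
75	APC	tissue	c.1213C>T	52.7
75	APC	tissue	c.1409-1G>A	28.7
75	APC	tissue	c.4348C>T	55.6
75	APC	plasma	c.1213C>T	9.7
75	APC	plasma	c.1409-1G>A	11.3
75	APC	plasma	c.4348C>T	9.0
75	KRAS	tissue	c.35G>T	57.7
75	KRAS	plasma	c.35G>T	17.2
78	APC	tissue	c.3340C>T	42.1
78	APC	tissue	c.4215dup	43.1
78	APC	plasma	c.3340C>T	19.5
78	APC	plasma	c.4215dup	20.7
78	APC	plasma	c.6747del	0.4
78	KRAS	tissue	c.35G>A	57.8
78	KRAS	plasma	c.35G>A	45.9
78	TP53	tissue	c.632C>T	45.7
78	TP53	tissue	c.454C>T	44.4
78	TP53	plasma	c.632C>T	22.9
78	TP53	plasma	c.454C>T	19.4
83	TP53	tissue	c.524G>A	35.0
83	TP53	plasma	c.524G>A	1.7
84	APC	tissue	c.1387dup	78.3
84	APC	plasma	c.1387dup	0.8
84	KRAS	tissue	c.35G>T	61.8
84	KRAS	plasma	c.35G>T	0.6
84	TP53	tissue	c.1024C>T	77.6
84	TP53	plasma	c.1024C>T	1.5
85	APC	tissue	c.4064_4065insA	81.5
85	APC	plasma	c.4064_4065insA	14.3
85	KRAS	tissue	c.437C>T	79.2
85	KRAS	plasma	c.437C>T	6.2
85	TP53	tissue	c.480_482del	80.1
85	TP53	plasma	c.480_482del	8.0
85	TP53	plasma	c.761T>G	0.2
85	TP53	plasma	c.743G>A	3.5
85	TP53	plasma	c.451C>A	0.2
85	TP53	plasma	c.379T>C	0.2
96	APC	tissue	c.1548+1G>T	29.7
96	APC	tissue	c.4127_4128del	62.9
96	APC	plasma	c.1548+1G>T	10
96	APC	plasma	c.4127_4128del	29.3
96	KRAS	tissue	c.34G>A	44.6
96	KRAS	plasma	c.34G>A	17
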