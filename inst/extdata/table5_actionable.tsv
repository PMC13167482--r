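# Matched tumor-tissue / plasma calls in potentially actionable genes (BRAF,
# PIK3CA, EGFR) for the same 16-patient cohort (patients 38, 55, 68, 73, 83
# and 85 had no detection in either sample and contribute no rows; the cohort
# size for patient-level denominators is 16). Transcribed from the published
# concordance evaluation this package models.
patient_id	gene	sample_type	hgvs_c	vaf_pct
14	BRAF	tissue	c.95_100del	23.4
29	BRAF	tissue	c.95_100del	15.8
32	PIK3CA	tissue	c.1633G>A	40.3
52	PIK3CA	tissue	c.1633G>A	13.2
53	BRAF	tissue	c.94G>C	25
53	BRAF	plasma	c.94G>C	11.8
59	EGFR	plasma	c.1159_1160del	0.3
75	PIK3CA	tissue	c.3140A>G	50.0
75	PIK3CA	plasma	c.3140A>G	12.0
78	BRAF	plasma	c.2257del	0.3
84	PIK3CA	plasma	c.1624G>A	0.6
96	BRAF	plasma	c.209G>A	9.6
96	EGFR	plasma	c.412A>G	0.5
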