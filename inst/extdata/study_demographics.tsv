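variable	statistic	HC	NSZ	VSZ
age_years	mean	32.36	31.22	33.61
age_years	sd	4.93	6.54	8.62
education_years	mean	12.48	12.78	11.56
education_years	sd	2.61	2.98	2.97
duration_months	mean	NA	16.1	59.89
duration_months	sd	NA	28.88	65.25
PANSS_total	mean	NA	86.3	112
PANSS_total	sd	NA	16.49	7.4
MOAS	mean	NA	14.96	29
MOAS	sd	NA	3.99	3.33
n	count	22	23	18
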