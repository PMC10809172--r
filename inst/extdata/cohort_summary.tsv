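cohort	n	n_female	age_mean	age_sd	bmi_mean	bmi_sd	energy_mean	energy_sd	alcohol_mean	mmds_mean	mmds_sd	dash_mean	dash_sd	hpdi_mean	hpdi_sd
WHI	1736	1736	64.2	7.05	29.8	6.02	1628	636	3.75	12.0	4.04	24.3	4.94	54.7	7.34
FHS	1843	1045	66.4	8.87	28.2	5.37	1841	573	10.2	12.1	4.45	24.4	4.67	52.1	6.71
REGICOR-450	573	285	57.9	11.44	27.2	3.93	2319	596	9.64	11.8	4.42	24.5	5.24	57.4	6.97
REGICOR-EPIC	269	139	56.0	7.03	28.3	5.87	2459	593	11.0	11.9	4.36	23.9	4.95	57.6	7.00
AIRWAVE	853	366	41.1	9.37	27.1	4.41	1925	482	15.9	11.8	4.29	23.9	5.04	55.7	7.35
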