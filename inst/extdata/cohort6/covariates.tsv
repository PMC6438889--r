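subject_id	group	age	sex	bdi	z_attention	z_executive	z_memory	z_visuospatial	z_language	mean_z	hub_strength
sub-001	A	66.44392	F	8.54381	1.99162	2.16331	1.89279	2.15672	1.83371	2.00763	0.18596
sub-002	A	65.54797	F	15.31341	0.13654	0.42572	0.12285	0.00279	0.35684	0.20895	0.05617
sub-003	A	59.32257	M	3.25121	0.73768	1.43222	0.54579	0.78888	0.7211	0.84513	0.10539
sub-004	B	68.95553	M	0.12193	-0.05565	-0.09205	-0.02988	-0.15612	0.57874	0.04901	0
sub-005	B	62.07157	F	4.68926	0.09912	-0.51242	0.18572	0.37241	0.14122	0.05721	0
sub-006	B	59.41441	M	3.79665	-0.31471	-0.14255	-0.12047	-0.79138	-0.06432	-0.28669	0
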