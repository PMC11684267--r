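# Reported SMR estimates: effect of CpG methylation (per SD increase) on
# gout risk (log-odds), as published with two-decimal beta and 95% CI and a
# rounded p-value. Used by the worked example that recovers the p-value
# from the interval under the normal approximation.
probe_id	gene_id	beta	ci_lower	ci_upper	pval_reported
cg25402137	ALDH3B1	-0.08	-0.16	0.00	0.044
cg02999224	SLC7A7	0.18	0.03	0.34	0.022
cg16465430	SLC7A7	0.07	0.00	0.14	0.048
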