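# B2m 3'UTR C-to-U validation, naive microglia: 6 predicted positions x 4 replicates
# edited-clone counts and undetected-position identities are synthetic placeholders;
# per-position detection fractions (replicates with >=1 edited clone) are the data of record
position	replicate	edited	total
2:122152740	1	2	30
2:122152740	2	2	30
2:122152740	3	0	30
2:122152740	4	0	30
2:122152742	1	2	30
2:122152742	2	0	30
2:122152742	3	0	30
2:122152742	4	0	30
2:122152871	1	2	30
2:122152871	2	2	30
2:122152871	3	0	30
2:122152871	4	0	30
2:122152682	1	0	30
2:122152682	2	0	30
2:122152682	3	0	30
2:122152682	4	0	30
2:122152687	1	0	30
2:122152687	2	0	30
2:122152687	3	0	30
2:122152687	4	0	30
2:122152707	1	0	30
2:122152707	2	0	30
2:122152707	3	0	30
2:122152707	4	0	30
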