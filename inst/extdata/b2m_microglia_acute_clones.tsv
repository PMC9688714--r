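# B2m 3'UTR C-to-U validation, acute EAE microglia: 19 predicted positions x 4 replicates
# edited-clone counts and undetected-position identities are synthetic placeholders;
# per-position detection fractions (replicates with >=1 edited clone) are the data of record
position	replicate	edited	total
2:122152682	1	2	30
2:122152682	2	2	30
2:122152682	3	2	30
2:122152682	4	0	30
2:122152687	1	2	30
2:122152687	2	0	30
2:122152687	3	0	30
2:122152687	4	0	30
2:122152707	1	2	30
2:122152707	2	0	30
2:122152707	3	0	30
2:122152707	4	0	30
2:122152740	1	2	30
2:122152740	2	2	30
2:122152740	3	2	30
2:122152740	4	2	30
2:122152742	1	2	30
2:122152742	2	2	30
2:122152742	3	2	30
2:122152742	4	0	30
2:122152751	1	2	30
2:122152751	2	0	30
2:122152751	3	0	30
2:122152751	4	0	30
2:122152871	1	2	30
2:122152871	2	2	30
2:122152871	3	2	30
2:122152871	4	0	30
2:122152912	1	2	30
2:122152912	2	0	30
2:122152912	3	0	30
2:122152912	4	0	30
2:122152928	1	2	30
2:122152928	2	0	30
2:122152928	3	0	30
2:122152928	4	0	30
2:122152700	1	0	30
2:122152700	2	0	30
2:122152700	3	0	30
2:122152700	4	0	30
2:122152715	1	0	30
2:122152715	2	0	30
2:122152715	3	0	30
2:122152715	4	0	30
2:122152725	1	0	30
2:122152725	2	0	30
2:122152725	3	0	30
2:122152725	4	0	30
2:122152760	1	0	30
2:122152760	2	0	30
2:122152760	3	0	30
2:122152760	4	0	30
2:122152780	1	0	30
2:122152780	2	0	30
2:122152780	3	0	30
2:122152780	4	0	30
2:122152800	1	0	30
2:122152800	2	0	30
2:122152800	3	0	30
2:122152800	4	0	30
2:122152850	1	0	30
2:122152850	2	0	30
2:122152850	3	0	30
2:122152850	4	0	30
2:122152880	1	0	30
2:122152880	2	0	30
2:122152880	3	0	30
2:122152880	4	0	30
2:122152900	1	0	30
2:122152900	2	0	30
2:122152900	3	0	30
2:122152900	4	0	30
2:122152940	1	0	30
2:122152940	2	0	30
2:122152940	3	0	30
2:122152940	4	0	30
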