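# B2m 3'UTR C-to-U validation, acute EAE whole brain: 11 edited positions x 3 samples
# edited-clone counts and undetected-position identities are synthetic placeholders;
# per-position detection fractions (replicates with >=1 edited clone) are the data of record
position	replicate	edited	total
2:122152682	1	2	30
2:122152682	2	0	30
2:122152682	3	0	30
2:122152694	1	2	30
2:122152694	2	0	30
2:122152694	3	0	30
2:122152740	1	2	30
2:122152740	2	2	30
2:122152740	3	2	30
2:122152742	1	2	30
2:122152742	2	0	30
2:122152742	3	0	30
2:122152745	1	2	30
2:122152745	2	0	30
2:122152745	3	0	30
2:122152751	1	2	30
2:122152751	2	0	30
2:122152751	3	0	30
2:122152759	1	2	30
2:122152759	2	0	30
2:122152759	3	0	30
2:122152763	1	2	30
2:122152763	2	2	30
2:122152763	3	0	30
2:122152845	1	2	30
2:122152845	2	0	30
2:122152845	3	0	30
2:122152871	1	2	30
2:122152871	2	2	30
2:122152871	3	2	30
2:122152928	1	2	30
2:122152928	2	2	30
2:122152928	3	0	30
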