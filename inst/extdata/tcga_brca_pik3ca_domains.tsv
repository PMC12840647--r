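domain	neutral_frac	observed_frac	enrichment	neutral_mean	observed_mean
ABD	0.0891	0.0170	0.19	-0.535	-0.167
C2	0.1509	0.1048	0.69	-0.726	-0.243
Helical	0.1666	0.3824	2.29	-0.492	0.778
Kinase	0.3402	0.4674	1.37	-0.350	-0.236
Other	0.1672	0.0283	0.17	-0.729	-0.600
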