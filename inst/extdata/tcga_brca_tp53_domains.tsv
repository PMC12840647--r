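domain	neutral_frac	observed_frac	enrichment	neutral_mean	observed_mean
CTD	0.0920	0.0000	0.00	-0.597	0.000
DBD	0.4487	0.9804	2.18	-0.772	-1.030
OD	0.1197	0.0147	0.12	-0.660	-2.000
Other	0.0702	0.0000	0.00	-0.845	0.000
PRD	0.1139	0.0000	0.00	-1.200	0.000
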