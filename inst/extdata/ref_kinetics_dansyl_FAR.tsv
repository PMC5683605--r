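enzyme_form	active_domains	enzyme_conc_nM	Km_uM	Km_se	kcat_per_s	kcat_se	kcat_over_Km	kcat_over_Km_se
rhCPD	I+II	2.5	153	16	12.5	0.5	0.082	0.012
E762Q	I	5.0	319	37	8.5	0.5	0.027	0.003
E350Q	II	20.0	844	139	7.0	0.9	0.008	0.001
E350Q/E762Q	none	100.0	NA	NA	NA	NA	NA	NA
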