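gene_id	domain	start	end
toygene	Nterm	1	100
toygene	Core	150	300
toygene	Cterm	320	480
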