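gene_id	contrast	mean_a	mean_b	printed_log2fc	definition
Solyc01g009680	OE_vs_EV	259.96	121.66	1.10	Lipoxygenase
Solyc01g007920	OE_vs_EV	383.01	252.28	0.60	Isochorismatase
Solyc03g042560	OE_vs_EV	157.66	74.40	1.08	Phenylalanine ammonia-lyase
Solyc03g007070	VIGS_vs_V1V2	86.91	231.66	-1.41	1-aminocyclopropane-1-carboxylate synthase
Solyc08g079750	VIGS_vs_V1V2	713.15	1285.27	-0.85	1-aminocyclopropane-1-carboxylate synthase
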