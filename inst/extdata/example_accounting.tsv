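sample	total_reads	n_gt10pct	low_quality	adapter5p_contamination	adapter3p_null_or_insert_null	polyATGC	clean_reads
SNT_1	13270313	615	54247	6166	262996	58340	12887949
SNT_2	13711506	915	24537	5279	105401	50154	13525220
SNT_3	17406422	1162	30069	11896	245857	65763	17051675
STH_1	15033708	1038	29023	6654	119728	76923	14800342
STH_2	15782638	1034	28626	9111	151666	81184	15511017
STH_3	15734878	1072	29159	6548	128713	70152	15499234
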