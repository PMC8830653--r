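population	total_runs	n_individuals	mean_coverage_mb	sd_coverage_mb	l_gen_gb	count_1_2mb	count_2_4mb	count_gt4mb
S21	145010	3770	66.53	12.20	2.45	109453	31307	4250
S22	84396	2096	73.32	13.77	2.45	60979	19338	4079
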