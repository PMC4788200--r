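dataset	n_samples	n_cases	n_controls	n_mirna	n_mrna	total_pairs	n_significant	pct_significant	sig_and_targets
COAD	444	436	8	325	14860	4829500	823121	17.04	47134
ESCA	191	178	13	338	18807	6356766	568914	8.95	30061
LIHC	407	357	50	343	14428	4948804	1156839	24.38	57675
READ	160	157	3	325	14973	4866225	423296	8.70	24941
STAD	443	406	37	330	18565	6126450	1390596	22.70	71464
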