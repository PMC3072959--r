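panel	class	group	count
queen_worker	orphan	queen	18
queen_worker	hymenoptera	queen	1
queen_worker	social_insect	queen	5
queen_worker	hymenoptera_conserved	queen	5
queen_worker	insect	queen	10
queen_worker	metazoa	queen	464
queen_worker	other	queen	160
queen_worker	orphan	worker	37
queen_worker	hymenoptera	worker	2
queen_worker	social_insect	worker	5
queen_worker	hymenoptera_conserved	worker	4
queen_worker	insect	worker	7
queen_worker	metazoa	worker	367
queen_worker	other	worker	116
queen_worker	orphan	no_difference	61
queen_worker	hymenoptera	no_difference	7
queen_worker	social_insect	no_difference	10
queen_worker	hymenoptera_conserved	no_difference	17
queen_worker	insect	no_difference	15
queen_worker	metazoa	no_difference	1339
queen_worker	other	no_difference	431
nurse_forager	orphan	nurse	21
nurse_forager	hymenoptera	nurse	4
nurse_forager	social_insect	nurse	4
nurse_forager	hymenoptera_conserved	nurse	6
nurse_forager	insect	nurse	10
nurse_forager	metazoa	nurse	564
nurse_forager	other	nurse	270
nurse_forager	orphan	forager	16
nurse_forager	hymenoptera	forager	5
nurse_forager	social_insect	forager	5
nurse_forager	hymenoptera_conserved	forager	4
nurse_forager	insect	forager	6
nurse_forager	metazoa	forager	326
nurse_forager	other	forager	142
hpg	orphan	hpg	2
hpg	hymenoptera	hpg	0
hpg	social_insect	hpg	1
hpg	hymenoptera_conserved	hpg	1
hpg	insect	hpg	1
hpg	metazoa	hpg	57
hpg	other	hpg	44
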