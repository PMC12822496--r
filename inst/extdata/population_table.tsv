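age_band	total	total_pct	first	first_pct	second	second_pct	third	third_pct
20-25	12010	22	7555	23	3844	20	611	19
26-30	24556	44	14793	44	8421	45	1342	43
31-35	12886	23	7603	23	4498	24	785	25
36-40	4715	9	2727	8	1675	9	313	10
41-45	1156	2	704	2	366	2	86	3
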