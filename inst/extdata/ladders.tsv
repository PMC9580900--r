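# plasmidkit gel ladders, format v1
# ladder_name <TAB> size_bp <TAB> relative_mass_weight
1kb	10000	1
1kb	8000	1
1kb	6000	1
1kb	5000	1
1kb	4000	1
1kb	3000	2
1kb	2500	1
1kb	2000	1
1kb	1500	1
1kb	1000	2
1kb	750	1
1kb	500	1
1kb	250	1
100bp	1500	1
100bp	1000	2
100bp	900	1
100bp	800	1
100bp	700	1
100bp	600	1
100bp	500	2
100bp	400	1
100bp	300	1
100bp	200	1
100bp	100	1
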