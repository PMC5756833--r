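species	n_cells	grade	dimorphism	protoplasmic_volume	M	b	a	S	ratio
Carteria palmata	1	Unicellular	Isogamy	5080	5080	5080	5080	10160	1
Chlamydomonas allensworthii	1	Unicellular	Anisogamy	950	950	950	59	1010	16
Chlamydomonas chlamydogama	1	Unicellular	Isogamy	1120	1120	560	560	1120	1
Chlamydomonas indica	1	Unicellular	Isogamy	733	733	183	183	367	1
Chlamydomonas microhalophila	1	Unicellular	Isogamy	1508	1508	754	754	1508	1
Chlamydomonas moewusii	1	Unicellular	isogamy	8370	8370	2093	2093	4185	1
Chlamydomonas reinhardtii	1	Unicellular	Isogamy	11000	11000	5500	5500	11000	1
Chlamydomonas sphagnicola	1	Unicellular	Oogamy	3591	3591	3591	225	3816	16
Chlamydomonas suboogama	1	Unicellular	Anisogamy	3054	3054	3054	191	3245	16
Chlorogonium mariae	1	Unicellular	Isogamy	524	524	131	131	262	1
Chloromonas chenangoensis	1	Unicellular	Isogamy	4009	4009	4009	4009	8018	1
Lobocharacium coloradoense	1	Unicellular	Isogamy	1734159	1734159	524	524	1047	1
Lobochlamys segnis	1	Unicellular	Isogamy	700	700	22	22	44	1
Oogamochlamys ettlii	1	Unicellular	Oogamy	6842	6842	6842	428	7270	16
Oogamochlamys gigantea	1	Unicellular	Oogamy	8181	8181	8181	128	8309	64
Oogamochlamys zimbabwiensis	1	Unicellular	Oogamy	4189	4189	4189	262	4451	16
Pseudocarteria corcontica	1	Unicellular	Isogamy	13360	13360	13360	13360	26719	1
Tetrabaena socialis	4	Colonial	Isogamy	11800	2950	738	738	1475	1
Stephanosphaera pluvialis	8	Colonial	Isogamy	10648	1331	83	83	166	1
Desmotetra antarctica	16	Colonial	Isogamy	147244	9203	575	575	1150	1
Desmotetra aureospora	16	Colonial	Isogamy	77584	4849	303	303	606	1
Gonium maiaprilis	16	colonial	Isogamy	28272	1767	221	221	442	1
Gonium pectorale	16	Colonial	Isogamy	75600	4725	2363	2363	4725	1
Gonium quadratum	16	Colonial	Isogamy	11200	700	697	697	1394	1
Gonium viridistellatum	16	Colonial	Isogamy	28300	1769	884	884	1769	1
Volvulina pringsheimii	16	Colonial	Isogamy	28300	1769	1767	1767	3534	1
Colemanosphaera charkowiensis	32	Colonial	Anisogamy	82318	2572	2572	80	2653	32
Eudorina elegans	32	Colonial	Anisogamy/internal	232000	7250	3625	57	3682	64
Gonium multicoccum	32	Colonial	Isogamy	97700	3053	3053	3053	6106	1
Pandorina morum	32	Colonial	Isogamy	294000	9188	574	574	1148	1
Platydorina caudata	32	Colonial	Anisogamy	262000	8188	4094	128	4222	32
Volvulina steinii	32	Colonial	Isogamy	70600	2206	2206	2206	4413	1
Pleodorina indica	64	Multicellular	Anisogamy/internal	357000	9200	1150	18	1168	64
Astrephomene gubernaculifera	128	Multicellular	Isogamy	6100000	48800	3050	3050	6100	1
Pleodorina japonica	128	Multicellular	Anisogamy/internal	1040000	14100	14100	110	14210	128
Volvox pocockiae	1500	Multicellular	Oogamy	2650000	113000	113000	1766	114766	64
Volvox tertius	2000	Multicellular	Oogamy	763000	655000	655000	20469	675469	32
Volvox carteri	3000	Multicellular	Oogamy	1570000	10300	10300	80	10380	128
Volvox aureus	3200	Multicellular	Oogamy	362000	7230	7230	226	7456	32
Volvox obversus	4000	Multicellular	Oogamy	2090000	38800	38800	303	39103	128
Volvox africanus	6000	Multicellular	Oogamy	963000	47700	47700	373	48073	128
Volvox capensis	20000	Multicellular	Oogamy	42100000	125000	125000	244	125244	512
Volvox globator	22000	Multicellular	Oogamy	737000	11000	11000	43	11043	256
Volvox dissipatrix	31800	Multicellular	Oogamy	133000000	33500	33500	131	33631	256
Volvox rousseletii	50000	Multicellular	Oogamy	105000000	14100	14100	28	14128	512
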