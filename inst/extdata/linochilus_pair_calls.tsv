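sister1	sister2	p_value	distribution	reported_divergence	age	age_low	age_high
L. phylicoides	L. lacunosus	0.4722	Allopatric	Geog. isolation	0.16	0.01	0.58
L. obtusus	L. venezuelensis	1.0000	Sympatric	Inconclusive	0.22	0.01	0.81
L. violaceus	L. cinerascens	0.2897	Allopatric	Geog. isolation	0.28	0.01	0.86
L. rosmarinifolius	L. cyparissias	-	Allopatric	Geog. isolation	-	-	-
L. floribundus	L. farallonensis/perijaensis	-	Allopatric	Geog. isolation	-	-	-
L. rhomboidalis	L. apiculatus	2.50E-09	Allopatric	Geog. isolation	0.59	0.01	1.54
L. alveolatus	L. costaricensis	1.0000	Allopatric	Geog. isolation	0.56	0.01	1.46
L. rhododendroides	L. schultzii	1.0000	Allopatric	Geog. isolation	0.92	0.02	2.14
L. tenuifolius	L. ellipticus	-	Allopatric	Geog. isolation	-	-	-
L. oblongifolius	L. mutiscuanus	0.4140	Allopatric	Geog. isolation	0.20	0.01	0.76
L. sp. nov. ANT	L. antioquensis	0.1663	Allopatric	Geog. isolation	0.52	0.01	1.47
L. huertasii	L. julianii	-	Allopatric	Geog. isolation	1.41	0.05	3.18
L. eriophorus	L. chrysotrichus	-	Allopatric	Geog. isolation	-	-	-
L. colombianus	L. glutinosus	1.20E-11	Sympatric	Ecological	2.97	0.11	6.17
L. romeroi	L. saxatilis	-	Sympatric	Inconclusive	-	-	-
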