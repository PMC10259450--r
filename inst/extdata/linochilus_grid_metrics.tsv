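sister1	sister2	overlap_0.1	overlap_0.05	asymmetry_0.1	asymmetry_0.05
L. phylicoides	L. lacunosus	0	0	10.7	16.4
L. obtusus	L. venezuelensis	0.4	0.2	1.0	1.1
L. violaceus	L. cinerascens	0	0	5.7	6.3
L. rosmarinifolius	L. cyparissias	0	0	21.8	25.3
L. floribundus	L. farallonensis	0	0	42.0	46.0
L. floribundus	L. perijaensis	0	0	42.5	46.6
L. rhomboidalis	L. apiculatus	0	0	1.7	1.5
L. alveolatus	L. costaricensis	0	0	15.2	8.1
L. rhododendroides	L. schultzii	0	0	4.0	5.2
L. tenuifolius	L. ellipticus	0	0	17.1	20.1
L. oblongifolius	L. mutiscuanus	0	0	3.0	4.0
L. sp. nov. ANT	L. antioquensis	0	0	1.0	1.0
L. huertasii	L. julianii	0	0	7.0	7.0
L. eriophorus	L. chrysotrichus	0	0	7.0	9.0
L. colombianus	L. glutinosus	0.2	0.2	2.6	2.6
L. romeroi	L. saxatilis	1.0	0	3.0	1.5
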