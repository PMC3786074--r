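taxon	accession	tribe	copy_number	footnotes
Acnistus arborescens	EU580954	Physaleae	2	a,b
Aureliana fasciculata	EU580961	Physaleae	2
Brachistus stramonifolius	EU580963	Physaleae	3
Brugmansia aurea	EU580965	Datureae	1	c
Brugmansia sanguinea	EU580966	Datureae	1	c
Capsicum baccatum	EU580969	Capsiceae	4	a,b
Capsicum chinense	EU603443	Capsiceae	4	d
Capsicum minutiflorum	EU580970	Capsiceae	6	d
Capsicum pubescens	AY348982	Capsiceae	6	b,d
Capsicum rhomboideum	EU580971	Capsiceae	1	e
Chamaesaracha coronopus	EU580978	Physaleae	4
Chamaesaracha sordida	EU580979	Physaleae	4
Cuatresia exiguiflora	EU580981	Physaleae	2
Cuatresia riparia	EU580982	Physaleae	2
Datura leichhardtii	EU580983	Datureae	1	f
Datura stramonium	EU580984	Datureae	1	f
Deprea sylvarum	EU580985	Physaleae	3
Discopodium penninervum	EU580986	Physaleae	4
Dunalia solanacea	EU580988	Physaleae	4
Eriolarynx lorenzii	EU580990	Physaleae	4
Iochroma australe	EU580999	Physaleae	4
Iochroma cardenasianum	EU581000	Datureae	1	f
Iochroma fuchsioides	EU581001	Physaleae	2
Iochroma umbellatum	EU581002	Physaleae	2
Jaltomata auriculata	EU581006	Solaneae	2	f
Jaltomata grandiflora	EU581007	Solaneae	2	f
Jalotmata procumbens	AY098695	Solaneae	1	a,b,f
Jaltomata sinuosa	DQ180418	Solaneae	2	f
Larnax subtriflora	EU581009	Physaleae	3
Leucophysalis grandiflora	EU581013	Physaleae	2
Leucophysalis nana	EU581014	Physaleae	2
Lycianthes biflora	EU581015	Capsiceae	2	g
Lycianthes ciliolata	EU581016	Capsiceae	4	h,i
Lycianthes glandulosa	EU581017	Capsiceae	3	g,i
Lycianthes heteroclita	DQ180414	Capsiceae	2	g,i
Lycianthes inaequilatera	EU581018	Capsiceae	6	h,i
Lycianthes multiflora	EU581019	Capsiceae	3	g,i
Lycianthes peduncularis	EU581020	Capsiceae	4	h,i
Lycianthes shanesii	EU581021	Capsiceae	1	g,h,i
Margaranthus solanaceus	EU581025	Physaleae	5	i
Nectouxia formosa	EU581031	Salpichroina*	1	a,b
Nothocestrum latifolium	EU581037	Physaleae	2
Nothocestrum longifolium	EU581038	Physaleae	3
Oryctes nevadensis	EU581039	Physaleae	3
Physalis alkekengi	DQ180420	Physaleae	2
Physalis carpenteri	EU581042	Physaleae	2
Physalis heterophylla	EU581043	Physaleae	2
Physalis peruviana	EU581044	Physaleae	4	a,b
Physalis philadelphica	EU581045	Physaleae	5	a,b
Quincula lobata	EU581051	Physaleae	1	a,b
Salpichroa origanifolia	EU581052	Salpichroina*	2	a,b
Saracha punctata	EU581053	Physaleae	4
Solanum abutiloides	AY266236	Solaneae	1	f
Solanum aviculare	HM006836	Solaneae	2	a,b,f
Solanum betaceum	DQ180426	Solaneae	1	f
Solanum dulcamara	HM006840	Solaneae	1	f
Solanum herculeum	DQ180466	Solaneae	2	f
Solanum lycopersicum	NC007898	Solaneae	1	f
Solanum melongena	EU176149	Solaneae	2	h,i
Solanum pseudocapsicum	DQ180436	Solaneae	1
Solanum torvum	AY266246	Solaneae	4	i
Solanum trisectum	JN130370	Solaneae	2
Solanum wendlandii	DQ180440	Solaneae	1
Tubocapsicum anomalum	EU581066	Physaleae	7
Vassobia dichotoma	EU581067	Physaleae	4
Witheringia cuneata	EU581070	Physaleae	2
Witheringia macrantha	EU581071	Physaleae	5
Witheringia meiantha	EU581072	Physaleae	4
Witheringia mexicana	EU581073	Physaleae	5
Witheringia solanacea	EU581074	Physaleae	3
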