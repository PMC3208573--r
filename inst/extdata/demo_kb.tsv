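source_id	source_kind	sign	target_id	target_kind	citation	quote
RGLR1	protein	+	g001	transcript	PMID:100001	RGLR1 overexpression induced this transcript
RGLR1	protein	+	g002	transcript	PMID:100002	RGLR1 overexpression induced this transcript
RGLR1	protein	+	g003	transcript	PMID:100003	RGLR1 overexpression induced this transcript
RGLR1	protein	+	g004	transcript	PMID:100004	
RGLR1	protein	+	g005	transcript	PMID:100005	
RGLR1	protein	+	g006	transcript	PMID:100006	
RGLR1	protein	+	g007	transcript	PMID:100007	
RGLR1	protein	+	g008	transcript	PMID:100008	
RGLR1	protein	+	g009	transcript	PMID:100009	
RGLR1	protein	+	g010	transcript	PMID:100010	
RGLR1	protein	+	g011	transcript	PMID:100011	
RGLR1	protein	+	g012	transcript	PMID:100012	
RGLR1	protein	+	g013	transcript	PMID:100013	
RGLR1	protein	+	g014	transcript	PMID:100014	
RGLR1	protein	+	g015	transcript	PMID:100015	
RGLR1	protein	+	g016	transcript	PMID:100016	
RGLR1	protein	+	g017	transcript	PMID:100017	
RGLR1	protein	+	g018	transcript	PMID:100018	
RGLR1	protein	+	g019	transcript	PMID:100019	
RGLR1	protein	+	g020	transcript	PMID:100020	
RGLR1	protein	+	g021	transcript	PMID:100021	
RGLR1	protein	+	g022	transcript	PMID:100022	
RGLR1	protein	+	g023	transcript	PMID:100023	
RGLR1	protein	+	g024	transcript	PMID:100024	
RGLR1	protein	+	g025	transcript	PMID:100025	
RGLR1	protein	+	g026	transcript	PMID:100026	
RGLR1	protein	+	g027	transcript	PMID:100027	
RGLR1	protein	+	g028	transcript	PMID:100028	
RGLR1	protein	+	g029	transcript	PMID:100029	
RGLR1	protein	+	g030	transcript	PMID:100030	
RGLR1	protein	+	g031	transcript	PMID:100031	
RGLR1	protein	+	g032	transcript	PMID:100032	
RGLR1	protein	+	g033	transcript	PMID:100033	
RGLR1	protein	+	g034	transcript	PMID:100034	
RGLR1	protein	+	g035	transcript	PMID:100035	
RGLR1	protein	+	g036	transcript	PMID:100036	
RGLR1	protein	+	g037	transcript	PMID:100037	
RGLR1	protein	+	g038	transcript	PMID:100038	
RGLR1	protein	+	g039	transcript	PMID:100039	
RGLR1	protein	+	g040	transcript	PMID:100040	
RGLR1	protein	+	g041	transcript	PMID:100041	
RGLR1	protein	+	g042	transcript	PMID:100042	
RGLR1	protein	+	g043	transcript	PMID:100043	
RGLR1	protein	+	g044	transcript	PMID:100044	
RGLR1	protein	+	g045	transcript	PMID:100045	
RGLR1	protein	+	g046	transcript	PMID:100046	
RGLR1	protein	+	g047	transcript	PMID:100047	
RGLR1	protein	+	g048	transcript	PMID:100048	
RGLR1	protein	+	g049	transcript	PMID:100049	
RGLR1	protein	+	g050	transcript	PMID:100050	
RGLR1	protein	+	g051	transcript	PMID:100051	
RGLR1	protein	-	g051	transcript	PMID:200051	conflicting report: repression observed
RGLR1	protein	+	g052	transcript	PMID:100052	
RGLR1	protein	-	g052	transcript	PMID:200052	conflicting report: repression observed
RGLR1	protein	+	g053	transcript	PMID:100053	
RGLR1	protein	-	g053	transcript	PMID:200053	conflicting report: repression observed
RGLR1	protein	+	g054	transcript	PMID:100054	
RGLR1	protein	-	g054	transcript	PMID:200054	conflicting report: repression observed
RGLR1	protein	+	g055	transcript	PMID:100055	
RGLR1	protein	-	g055	transcript	PMID:200055	conflicting report: repression observed
RGLR1	protein	+	g056	transcript	PMID:100056	
RGLR1	protein	-	g056	transcript	PMID:200056	conflicting report: repression observed
RGLR2	protein	+	g057	transcript	PMID:300057	
RGLR2	protein	+	g058	transcript	PMID:300058	
RGLR2	protein	+	g059	transcript	PMID:300059	
RGLR2	protein	+	g060	transcript	PMID:300060	
RGLR2	protein	+	g061	transcript	PMID:300061	
RGLR2	protein	+	g062	transcript	PMID:300062	
RGLR2	protein	+	g063	transcript	PMID:300063	
RGLR2	protein	+	g064	transcript	PMID:300064	
RGLR2	protein	+	g065	transcript	PMID:300065	
RGLR2	protein	+	g066	transcript	PMID:300066	
RGLR2	protein	+	g067	transcript	PMID:300067	
RGLR2	protein	+	g068	transcript	PMID:300068	
RGLR2	protein	+	g069	transcript	PMID:300069	
RGLR2	protein	+	g070	transcript	PMID:300070	
RGLR2	protein	+	g071	transcript	PMID:300071	
RGLR2	protein	+	g072	transcript	PMID:300072	
RGLR2	protein	+	g073	transcript	PMID:300073	
RGLR2	protein	+	g074	transcript	PMID:300074	
RGLR2	protein	+	g075	transcript	PMID:300075	
RGLR2	protein	+	g076	transcript	PMID:300076	
RGLR2	protein	+	g077	transcript	PMID:300077	
RGLR2	protein	+	g078	transcript	PMID:300078	
RGLR2	protein	+	g079	transcript	PMID:300079	
RGLR2	protein	+	g080	transcript	PMID:300080	
RGLR2	protein	+	g081	transcript	PMID:300081	
RGLR2	protein	+	g082	transcript	PMID:300082	
RGLR2	protein	+	g083	transcript	PMID:300083	
RGLR2	protein	+	g084	transcript	PMID:300084	
RGLR2	protein	+	g085	transcript	PMID:300085	
RGLR2	protein	+	g086	transcript	PMID:300086	
RGLR2	protein	+	g087	transcript	PMID:300087	
RGLR2	protein	+	g088	transcript	PMID:300088	
RGLR2	protein	+	g089	transcript	PMID:300089	
RGLR2	protein	+	g090	transcript	PMID:300090	
RGLR2	protein	+	g091	transcript	PMID:300091	
RGLR2	protein	+	g092	transcript	PMID:300092	
RGLR2	protein	+	g093	transcript	PMID:300093	
RGLR2	protein	+	g094	transcript	PMID:300094	
RGLR2	protein	+	g095	transcript	PMID:300095	
RGLR2	protein	+	g096	transcript	PMID:300096	
RGLR2	protein	+	g097	transcript	PMID:300097	
RGLR2	protein	+	g098	transcript	PMID:300098	
RGLR2	protein	+	g099	transcript	PMID:300099	
RGLR2	protein	+	g100	transcript	PMID:300100	
RGLR2	protein	+	g101	transcript	PMID:300101	
RGLR2	protein	+	g102	transcript	PMID:300102	
RGLR2	protein	+	g103	transcript	PMID:300103	
RGLR2	protein	+	g104	transcript	PMID:300104	
RGLR2	protein	+	g105	transcript	PMID:300105	
RGLR2	protein	+	g106	transcript	PMID:300106	
RGLR2	protein	+	g107	transcript	PMID:300107	
RGLR2	protein	+	g108	transcript	PMID:300108	
RGLR2	protein	+	g109	transcript	PMID:300109	
RGLR2	protein	+	g110	transcript	PMID:300110	
RGLR2	protein	+	g111	transcript	PMID:300111	
RGLR2	protein	+	g112	transcript	PMID:300112	
RGLR2	protein	+	g113	transcript	PMID:300113	
RGLR2	protein	+	g114	transcript	PMID:300114	
RGLR2	protein	+	g115	transcript	PMID:300115	
RGLR2	protein	+	g116	transcript	PMID:300116	
RGLR2	protein	+	g117	transcript	PMID:300117	
RGLR2	protein	+	g118	transcript	PMID:300118	
RGLR2	protein	+	g119	transcript	PMID:300119	
RGLR2	protein	+	g120	transcript	PMID:300120	
RGLR2	protein	+	g121	transcript	PMID:300121	
RGLR2	protein	+	g122	transcript	PMID:300122	
RGLR2	protein	+	g123	transcript	PMID:300123	
RGLR2	protein	+	g124	transcript	PMID:300124	
RGLR2	protein	+	g125	transcript	PMID:300125	
RGLR2	protein	+	g126	transcript	PMID:300126	
RGLR2	protein	+	g127	transcript	PMID:300127	
RGLR2	protein	+	g128	transcript	PMID:300128	
RGLR2	protein	+	g129	transcript	PMID:300129	
RGLR2	protein	+	g130	transcript	PMID:300130	
RGLR2	protein	+	g131	transcript	PMID:300131	
RGLR2	protein	+	g132	transcript	PMID:300132	
RGLR2	protein	+	g133	transcript	PMID:300133	
RGLR2	protein	+	g134	transcript	PMID:300134	
RGLR2	protein	+	g135	transcript	PMID:300135	
RGLR2	protein	+	g136	transcript	PMID:300136	
RGLR2	protein	+	g137	transcript	PMID:300137	
RGLR2	protein	+	g138	transcript	PMID:300138	
RGLR2	protein	+	g139	transcript	PMID:300139	
RGLR2	protein	+	g140	transcript	PMID:300140	
RGLR2	protein	+	g141	transcript	PMID:300141	
RGLR2	protein	+	g142	transcript	PMID:300142	
RGLR2	protein	+	g143	transcript	PMID:300143	
RGLR2	protein	+	g144	transcript	PMID:300144	
RGLR2	protein	+	g145	transcript	PMID:300145	
RGLR2	protein	+	g146	transcript	PMID:300146	
RGLR2	protein	+	g147	transcript	PMID:300147	
RGLR2	protein	+	g148	transcript	PMID:300148	
RGLR2	protein	+	g149	transcript	PMID:300149	
RGLR2	protein	+	g150	transcript	PMID:300150	
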