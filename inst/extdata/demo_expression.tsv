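gene_id	log2_fc	adj_p
g001	-1	0.001
g002	-1	0.001
g003	-1	0.001
g004	-1	0.001
g005	-1	0.001
g006	-1	0.001
g007	-1	0.001
g008	-1	0.001
g009	-1	0.001
g010	-1	0.001
g011	-1	0.001
g012	-1	0.001
g013	-1	0.001
g014	-1	0.001
g015	-1	0.001
g016	-1	0.001
g017	-1	0.001
g018	-1	0.001
g019	-1	0.001
g020	-1	0.001
g021	-1	0.001
g022	-1	0.001
g023	-1	0.001
g024	-1	0.001
g025	-1	0.001
g026	-1	0.001
g027	-1	0.001
g028	-1	0.001
g029	-1	0.001
g030	-1	0.001
g031	-1	0.001
g032	-1	0.001
g033	-1	0.001
g034	-1	0.001
g035	-1	0.001
g036	-1	0.001
g037	1	0.001
g038	1	0.001
g039	1	0.001
g040	1	0.001
g041	1	0.001
g042	1	0.001
g043	1	0.001
g044	1	0.001
g045	1	0.001
g046	1	0.001
g047	1	0.001
g048	1	0.001
g049	1	0.001
g050	1	0.001
g051	1	0.001
g052	-1	0.001
g053	1	0.001
g054	-1	0.001
g055	1	0.001
g056	-1	0.001
g057	0.05	0.8
g058	0.05	0.8
g059	0.05	0.8
g060	0.05	0.8
g061	0.05	0.8
g062	0.05	0.8
g063	0.05	0.8
g064	0.05	0.8
g065	0.05	0.8
g066	0.05	0.8
g067	0.05	0.8
g068	0.05	0.8
g069	0.05	0.8
g070	0.05	0.8
g071	0.05	0.8
g072	0.05	0.8
g073	0.05	0.8
g074	0.05	0.8
g075	0.05	0.8
g076	0.05	0.8
g077	0.05	0.8
g078	0.05	0.8
g079	0.05	0.8
g080	0.05	0.8
g081	0.05	0.8
g082	0.05	0.8
g083	0.05	0.8
g084	0.05	0.8
g085	0.05	0.8
g086	0.05	0.8
g087	0.05	0.8
g088	0.05	0.8
g089	0.05	0.8
g090	0.05	0.8
g091	0.05	0.8
g092	0.05	0.8
g093	0.05	0.8
g094	0.05	0.8
g095	0.05	0.8
g096	0.05	0.8
g097	0.05	0.8
g098	0.05	0.8
g099	0.05	0.8
g100	0.05	0.8
g101	0.05	0.8
g102	0.05	0.8
g103	0.05	0.8
g104	0.05	0.8
g105	0.05	0.8
g106	0.05	0.8
g107	0.05	0.8
g108	0.05	0.8
g109	0.05	0.8
g110	0.05	0.8
g111	0.05	0.8
g112	0.05	0.8
g113	0.05	0.8
g114	0.05	0.8
g115	0.05	0.8
g116	0.05	0.8
g117	0.05	0.8
g118	0.05	0.8
g119	0.05	0.8
g120	0.05	0.8
g121	0.05	0.8
g122	0.05	0.8
g123	0.05	0.8
g124	0.05	0.8
g125	0.05	0.8
g126	0.05	0.8
g127	0.05	0.8
g128	0.05	0.8
g129	0.05	0.8
g130	0.05	0.8
g131	0.05	0.8
g132	0.05	0.8
g133	0.05	0.8
g134	0.05	0.8
g135	0.05	0.8
g136	0.05	0.8
g137	0.05	0.8
g138	0.05	0.8
g139	0.05	0.8
g140	0.05	0.8
g141	0.05	0.8
g142	0.05	0.8
g143	0.05	0.8
g144	0.05	0.8
g145	0.05	0.8
g146	0.05	0.8
g147	0.05	0.8
g148	0.05	0.8
g149	0.05	0.8
g150	0.05	0.8
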