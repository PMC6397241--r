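# boescan synthetic fixture: 263 suppressor->query edges, 38 queries bypassed
# generated by tools/make_fixtures.R (fixed seed)
suppressor	query	type
s012	q001	OP-BOE
s028	q001	T-BOE-insertion
s030	q001	T-BOE-deletion
s089	q001	OP-BOE
s131	q001	T-BOE-insertion
s137	q001	OP-BOE
s014	q002	T-BOE-deletion
s032	q002	OP-BOE
s033	q002	C-BOE
s035	q002	OP-BOE
s048	q002	T-BOE-insertion
s122	q002	OP-BOE
s134	q002	T-BOE-deletion
s153	q002	T-BOE-deletion
s007	q003	OP-BOE
s016	q003	OP-BOE
s030	q003	C-BOE
s036	q003	T-BOE-insertion
s076	q003	T-BOE-deletion
s081	q003	T-BOE-insertion
s083	q003	OP-BOE
s106	q003	OP-BOE
s141	q003	T-BOE-insertion
s151	q003	OP-BOE
s154	q003	T-BOE-insertion
s004	q004	T-BOE-deletion
s040	q004	OP-BOE
s041	q004	T-BOE-deletion
s043	q004	T-BOE-deletion
s051	q004	T-BOE-deletion
s067	q004	T-BOE-insertion
s068	q004	T-BOE-deletion
s072	q004	OP-BOE
s086	q004	T-BOE-insertion
s117	q004	C-BOE
s126	q004	C-BOE
s008	q005	T-BOE-deletion
s017	q005	T-BOE-deletion
s071	q005	C-BOE
s097	q005	T-BOE-deletion
s108	q005	T-BOE-deletion
s109	q005	OP-BOE
s116	q005	T-BOE-deletion
s123	q005	T-BOE-insertion
s132	q005	T-BOE-deletion
s147	q005	OP-BOE
s157	q005	T-BOE-insertion
s039	q006	OP-BOE
s045	q006	OP-BOE
s051	q006	T-BOE-deletion
s013	q007	OP-BOE
s027	q007	OP-BOE
s034	q007	OP-BOE
s075	q007	OP-BOE
s083	q007	C-BOE
s023	q008	T-BOE-deletion
s026	q008	T-BOE-deletion
s044	q008	T-BOE-insertion
s092	q008	T-BOE-deletion
s120	q008	OP-BOE
s126	q008	OP-BOE
s136	q008	T-BOE-deletion
s024	q009	T-BOE-deletion
s042	q009	C-BOE
s059	q009	T-BOE-deletion
s068	q009	OP-BOE
s077	q009	C-BOE
s086	q009	OP-BOE
s090	q009	OP-BOE
s114	q009	OP-BOE
s138	q009	OP-BOE
s015	q010	OP-BOE
s028	q010	OP-BOE
s055	q010	OP-BOE
s061	q010	T-BOE-deletion
s077	q010	T-BOE-insertion
s083	q010	OP-BOE
s102	q010	OP-BOE
s125	q010	OP-BOE
s019	q011	T-BOE-insertion
s117	q011	T-BOE-deletion
s155	q011	OP-BOE
s069	q012	T-BOE-deletion
s111	q012	OP-BOE
s003	q013	OP-BOE
s020	q013	T-BOE-insertion
s044	q013	T-BOE-insertion
s062	q013	OP-BOE
s078	q013	OP-BOE
s129	q013	T-BOE-insertion
s053	q014	T-BOE-deletion
s057	q014	T-BOE-insertion
s073	q014	OP-BOE
s078	q014	OP-BOE
s079	q014	T-BOE-insertion
s138	q014	T-BOE-deletion
s038	q015	T-BOE-deletion
s063	q015	T-BOE-deletion
s065	q015	OP-BOE
s066	q015	T-BOE-deletion
s074	q015	T-BOE-deletion
s084	q015	C-BOE
s094	q015	T-BOE-deletion
s122	q015	OP-BOE
s124	q015	OP-BOE
s132	q015	T-BOE-insertion
s143	q015	OP-BOE
s019	q016	T-BOE-deletion
s060	q016	T-BOE-insertion
s101	q016	OP-BOE
s146	q016	T-BOE-deletion
s021	q017	T-BOE-deletion
s052	q017	C-BOE
s104	q017	T-BOE-insertion
s121	q017	OP-BOE
s126	q017	OP-BOE
s138	q017	T-BOE-deletion
s147	q017	OP-BOE
s006	q018	T-BOE-insertion
s058	q018	T-BOE-deletion
s070	q018	C-BOE
s090	q018	C-BOE
s104	q018	OP-BOE
s113	q018	OP-BOE
s125	q018	C-BOE
s008	q019	T-BOE-deletion
s029	q019	T-BOE-deletion
s031	q019	OP-BOE
s047	q019	OP-BOE
s054	q019	T-BOE-deletion
s125	q019	OP-BOE
s133	q019	OP-BOE
s135	q019	OP-BOE
s006	q020	OP-BOE
s009	q020	T-BOE-deletion
s069	q020	OP-BOE
s089	q020	OP-BOE
s131	q020	OP-BOE
s005	q021	OP-BOE
s007	q021	T-BOE-insertion
s017	q021	T-BOE-insertion
s022	q021	C-BOE
s046	q021	OP-BOE
s150	q021	OP-BOE
s156	q021	OP-BOE
s157	q021	T-BOE-deletion
s037	q022	OP-BOE
s047	q022	OP-BOE
s052	q022	OP-BOE
s076	q022	OP-BOE
s100	q022	C-BOE
s145	q022	T-BOE-deletion
s154	q022	T-BOE-insertion
s005	q023	OP-BOE
s028	q023	OP-BOE
s097	q023	OP-BOE
s107	q023	T-BOE-insertion
s130	q023	OP-BOE
s148	q023	C-BOE
s149	q023	C-BOE
s044	q024	T-BOE-deletion
s063	q024	OP-BOE
s136	q024	T-BOE-deletion
s015	q025	OP-BOE
s025	q025	T-BOE-deletion
s086	q025	T-BOE-insertion
s093	q025	OP-BOE
s128	q025	T-BOE-deletion
s138	q025	C-BOE
s010	q026	OP-BOE
s012	q026	OP-BOE
s018	q026	T-BOE-deletion
s095	q026	T-BOE-insertion
s128	q026	OP-BOE
s140	q026	T-BOE-deletion
s002	q027	T-BOE-insertion
s020	q027	OP-BOE
s063	q027	OP-BOE
s078	q027	OP-BOE
s096	q027	C-BOE
s099	q027	OP-BOE
s104	q027	T-BOE-deletion
s127	q027	OP-BOE
s133	q027	OP-BOE
s033	q028	T-BOE-deletion
s035	q028	OP-BOE
s050	q028	OP-BOE
s082	q028	T-BOE-insertion
s112	q028	T-BOE-insertion
s116	q028	OP-BOE
s127	q028	C-BOE
s128	q028	OP-BOE
s130	q028	T-BOE-deletion
s033	q029	T-BOE-deletion
s043	q029	OP-BOE
s092	q029	OP-BOE
s102	q029	C-BOE
s142	q029	OP-BOE
s066	q030	T-BOE-deletion
s088	q030	T-BOE-deletion
s129	q030	T-BOE-deletion
s138	q030	OP-BOE
s140	q030	T-BOE-deletion
s141	q030	C-BOE
s004	q031	OP-BOE
s049	q031	OP-BOE
s060	q031	OP-BOE
s083	q031	T-BOE-deletion
s091	q031	OP-BOE
s096	q031	OP-BOE
s118	q031	T-BOE-insertion
s129	q031	OP-BOE
s025	q032	T-BOE-deletion
s050	q032	OP-BOE
s085	q032	T-BOE-deletion
s087	q032	OP-BOE
s144	q032	T-BOE-deletion
s148	q032	OP-BOE
s154	q032	T-BOE-deletion
s002	q033	T-BOE-deletion
s015	q033	T-BOE-deletion
s032	q033	T-BOE-deletion
s077	q033	C-BOE
s081	q033	T-BOE-deletion
s098	q033	T-BOE-deletion
s109	q033	OP-BOE
s110	q033	OP-BOE
s119	q033	T-BOE-insertion
s011	q034	C-BOE
s019	q034	OP-BOE
s025	q034	OP-BOE
s031	q034	OP-BOE
s034	q034	T-BOE-deletion
s040	q034	T-BOE-deletion
s064	q034	C-BOE
s092	q034	T-BOE-deletion
s105	q034	OP-BOE
s137	q034	T-BOE-deletion
s145	q034	T-BOE-insertion
s001	q035	OP-BOE
s024	q035	T-BOE-deletion
s056	q035	T-BOE-deletion
s091	q035	C-BOE
s103	q035	C-BOE
s115	q035	T-BOE-deletion
s127	q035	T-BOE-deletion
s049	q036	T-BOE-deletion
s068	q036	C-BOE
s123	q036	OP-BOE
s138	q036	OP-BOE
s139	q036	T-BOE-deletion
s146	q036	OP-BOE
s090	q037	T-BOE-deletion
s121	q037	T-BOE-insertion
s044	q038	OP-BOE
s058	q038	T-BOE-deletion
s061	q038	C-BOE
s080	q038	OP-BOE
s106	q038	T-BOE-deletion
s133	q038	OP-BOE
s148	q038	OP-BOE
s152	q038	T-BOE-insertion
s157	q038	OP-BOE
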