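# boescan synthetic fixture: GO-slim map; mitochondrial_translation = 7 bypassable
# generated by tools/make_fixtures.R (fixed seed)
gene_id	term
q001	mitochondrial_translation
q002	mitochondrial_translation
q003	mitochondrial_translation
q004	mitochondrial_translation
q005	mitochondrial_translation
q006	mitochondrial_translation
q007	mitochondrial_translation
q069	term_09
q004	term_01
q036	term_11
q126	term_02
q035	term_10
q023	term_03
q077	term_03
q002	term_04
q078	term_05
q086	term_07
q045	term_11
q082	term_03
q065	term_03
q053	term_11
q080	term_12
q128	term_03
q091	term_04
q103	term_12
q041	term_12
q041	term_08
q071	term_07
q082	term_07
q129	term_08
q125	term_04
q132	term_04
q050	term_04
q008	term_08
q028	term_12
q050	term_03
q093	term_07
q011	term_07
q096	term_03
q026	term_04
q010	term_09
q096	term_02
q131	term_01
q066	term_03
q042	term_03
q035	term_04
q068	term_08
q043	term_12
q094	term_12
q071	term_09
q037	term_07
q051	term_11
q014	term_06
q125	term_06
q057	term_05
q023	term_09
q045	term_04
q055	term_12
q059	term_11
q071	term_08
q102	term_02
q125	term_12
q018	term_07
q077	term_01
q081	term_04
q025	term_02
q131	term_05
q057	term_12
q025	term_08
q081	term_06
q001	term_05
q004	term_07
q021	term_01
q062	term_12
q053	term_01
q053	term_02
q021	term_07
q142	term_11
q031	term_04
q136	term_06
q016	term_03
q058	term_07
q041	term_09
q118	term_09
q046	term_04
q135	term_06
q109	term_11
q020	term_09
q112	term_03
q016	term_10
q078	term_10
q094	term_09
q087	term_01
q013	term_06
q133	term_06
q045	term_03
q091	term_12
q131	term_10
q081	term_02
q064	term_12
q117	term_10
q072	term_05
q014	term_08
q099	term_12
q075	term_12
q055	term_03
q087	term_02
q119	term_06
q021	term_06
q115	term_05
q132	term_01
q030	term_01
q002	term_05
q141	term_12
q132	term_07
q103	term_11
q040	term_07
q104	term_03
q080	term_10
q048	term_07
q138	term_06
q065	term_04
q116	term_09
q060	term_01
q018	term_10
q038	term_01
q012	term_11
q068	term_01
q099	term_04
q033	term_09
q098	term_01
q093	term_05
q032	term_10
q100	term_09
q047	term_06
q081	term_08
q026	term_02
q106	term_10
q119	term_12
q017	term_12
q051	term_02
q071	term_01
q069	term_05
q109	term_12
q073	term_11
q033	term_04
q069	term_02
q029	term_01
q120	term_05
q116	term_03
q066	term_04
q093	term_06
q113	term_01
q093	term_10
q010	term_07
q120	term_12
q097	term_11
q088	term_09
q022	term_12
q096	term_05
q050	term_10
q015	term_02
q033	term_07
q062	term_02
q037	term_05
q108	term_10
q065	term_08
q139	term_01
q067	term_12
q126	term_09
q006	term_05
q118	term_02
q070	term_07
q031	term_12
q072	term_11
q052	term_07
q087	term_04
q086	term_06
q006	term_11
q058	term_04
q123	term_09
q121	term_06
q027	term_07
q088	term_05
q080	term_08
q001	term_03
q003	term_02
q009	term_09
q076	term_06
q005	term_04
q115	term_03
q124	term_06
q119	term_08
q136	term_11
q021	term_09
q001	term_10
q066	term_09
q110	term_03
q079	term_03
q043	term_03
q006	term_08
q062	term_11
q121	term_03
q135	term_05
q059	term_04
q125	term_11
q100	term_06
q060	term_06
q119	term_03
q076	term_08
q064	term_09
q069	term_01
q015	term_12
q104	term_08
q049	term_06
q061	term_03
q040	term_11
q108	term_05
q061	term_11
q035	term_02
q001	term_06
q092	term_09
q017	term_02
q111	term_09
q021	term_10
q048	term_08
q113	term_02
q009	term_05
q050	term_07
q134	term_06
q033	term_05
q016	term_01
q016	term_08
q134	term_12
q011	term_09
q026	term_03
q102	term_08
q012	term_01
q089	term_09
q125	term_07
q129	term_04
q056	term_06
q079	term_11
q089	term_01
q049	term_08
q082	term_11
q029	term_06
q044	term_05
q072	term_02
q052	term_12
q098	term_03
q013	term_09
q115	term_02
q127	term_08
q036	term_05
q139	term_09
q049	term_01
q030	term_05
q035	term_11
q052	term_09
q026	term_12
q127	term_06
q142	term_10
q037	term_09
q111	term_12
q084	term_03
q135	term_02
q042	term_05
q016	term_02
q030	term_09
q131	term_08
q006	term_10
q109	term_02
q089	term_11
q140	term_05
q065	term_09
q029	term_11
q070	term_08
q059	term_06
q038	term_03
q057	term_10
q033	term_01
q136	term_03
q064	term_03
q078	term_06
q113	term_04
q007	term_01
q043	term_04
q014	term_02
q021	term_08
q120	term_02
q018	term_05
q120	term_01
q122	term_12
q095	term_11
q070	term_10
q073	term_03
q127	term_09
q119	term_09
q009	term_02
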