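# boescan synthetic fixture: 142 screened genes, 38 bypassable
# generated by tools/make_fixtures.R (fixed seed)
gene_id	screened	bypassable	sc_one_to_one	sc_ortholog_status
q001	TRUE	TRUE	TRUE	non-essential
q002	TRUE	TRUE	TRUE	non-essential
q003	TRUE	TRUE	TRUE	non-essential
q004	TRUE	TRUE	TRUE	non-essential
q005	TRUE	TRUE	TRUE	non-essential
q006	TRUE	TRUE	TRUE	non-essential
q007	TRUE	TRUE	TRUE	non-essential
q008	TRUE	TRUE	TRUE	non-essential
q009	TRUE	TRUE	TRUE	non-essential
q010	TRUE	TRUE	TRUE	non-essential
q011	TRUE	TRUE	TRUE	non-essential
q012	TRUE	TRUE	TRUE	non-essential
q013	TRUE	TRUE	TRUE	non-essential
q014	TRUE	TRUE	TRUE	non-essential
q015	TRUE	TRUE	TRUE	non-essential
q016	TRUE	TRUE	TRUE	non-essential
q017	TRUE	TRUE	TRUE	non-essential
q018	TRUE	TRUE	TRUE	non-essential
q019	TRUE	TRUE	TRUE	non-essential
q020	TRUE	TRUE	TRUE	non-essential
q021	TRUE	TRUE	TRUE	non-essential
q022	TRUE	TRUE	TRUE	non-essential
q023	TRUE	TRUE	TRUE	non-essential
q024	TRUE	TRUE	TRUE	non-essential
q025	TRUE	TRUE	TRUE	essential
q026	TRUE	TRUE	TRUE	essential
q027	TRUE	TRUE	TRUE	essential
q028	TRUE	TRUE	TRUE	essential
q029	TRUE	TRUE	TRUE	essential
q030	TRUE	TRUE	TRUE	essential
q031	TRUE	TRUE	TRUE	essential
q032	TRUE	TRUE	FALSE	none
q033	TRUE	TRUE	FALSE	none
q034	TRUE	TRUE	FALSE	none
q035	TRUE	TRUE	FALSE	none
q036	TRUE	TRUE	FALSE	none
q037	TRUE	TRUE	FALSE	none
q038	TRUE	TRUE	FALSE	none
q039	TRUE	FALSE	TRUE	non-essential
q040	TRUE	FALSE	TRUE	non-essential
q041	TRUE	FALSE	TRUE	non-essential
q042	TRUE	FALSE	TRUE	non-essential
q043	TRUE	FALSE	TRUE	non-essential
q044	TRUE	FALSE	TRUE	non-essential
q045	TRUE	FALSE	TRUE	non-essential
q046	TRUE	FALSE	TRUE	non-essential
q047	TRUE	FALSE	TRUE	non-essential
q048	TRUE	FALSE	TRUE	non-essential
q049	TRUE	FALSE	TRUE	non-essential
q050	TRUE	FALSE	TRUE	non-essential
q051	TRUE	FALSE	TRUE	non-essential
q052	TRUE	FALSE	TRUE	essential
q053	TRUE	FALSE	TRUE	essential
q054	TRUE	FALSE	TRUE	essential
q055	TRUE	FALSE	TRUE	essential
q056	TRUE	FALSE	TRUE	essential
q057	TRUE	FALSE	TRUE	essential
q058	TRUE	FALSE	TRUE	essential
q059	TRUE	FALSE	TRUE	essential
q060	TRUE	FALSE	TRUE	essential
q061	TRUE	FALSE	TRUE	essential
q062	TRUE	FALSE	TRUE	essential
q063	TRUE	FALSE	TRUE	essential
q064	TRUE	FALSE	TRUE	essential
q065	TRUE	FALSE	TRUE	essential
q066	TRUE	FALSE	TRUE	essential
q067	TRUE	FALSE	TRUE	essential
q068	TRUE	FALSE	TRUE	essential
q069	TRUE	FALSE	TRUE	essential
q070	TRUE	FALSE	TRUE	essential
q071	TRUE	FALSE	TRUE	essential
q072	TRUE	FALSE	TRUE	essential
q073	TRUE	FALSE	TRUE	essential
q074	TRUE	FALSE	TRUE	essential
q075	TRUE	FALSE	TRUE	essential
q076	TRUE	FALSE	TRUE	essential
q077	TRUE	FALSE	TRUE	essential
q078	TRUE	FALSE	TRUE	essential
q079	TRUE	FALSE	TRUE	essential
q080	TRUE	FALSE	TRUE	essential
q081	TRUE	FALSE	TRUE	essential
q082	TRUE	FALSE	TRUE	essential
q083	TRUE	FALSE	TRUE	essential
q084	TRUE	FALSE	TRUE	essential
q085	TRUE	FALSE	TRUE	essential
q086	TRUE	FALSE	TRUE	essential
q087	TRUE	FALSE	TRUE	essential
q088	TRUE	FALSE	TRUE	essential
q089	TRUE	FALSE	TRUE	essential
q090	TRUE	FALSE	TRUE	essential
q091	TRUE	FALSE	TRUE	essential
q092	TRUE	FALSE	TRUE	essential
q093	TRUE	FALSE	TRUE	essential
q094	TRUE	FALSE	TRUE	essential
q095	TRUE	FALSE	TRUE	essential
q096	TRUE	FALSE	TRUE	essential
q097	TRUE	FALSE	TRUE	essential
q098	TRUE	FALSE	TRUE	essential
q099	TRUE	FALSE	TRUE	essential
q100	TRUE	FALSE	TRUE	essential
q101	TRUE	FALSE	TRUE	essential
q102	TRUE	FALSE	TRUE	essential
q103	TRUE	FALSE	TRUE	essential
q104	TRUE	FALSE	TRUE	essential
q105	TRUE	FALSE	TRUE	essential
q106	TRUE	FALSE	TRUE	essential
q107	TRUE	FALSE	TRUE	essential
q108	TRUE	FALSE	TRUE	essential
q109	TRUE	FALSE	TRUE	essential
q110	TRUE	FALSE	TRUE	essential
q111	TRUE	FALSE	TRUE	essential
q112	TRUE	FALSE	TRUE	essential
q113	TRUE	FALSE	TRUE	essential
q114	TRUE	FALSE	TRUE	essential
q115	TRUE	FALSE	TRUE	essential
q116	TRUE	FALSE	TRUE	essential
q117	TRUE	FALSE	TRUE	essential
q118	TRUE	FALSE	TRUE	essential
q119	TRUE	FALSE	TRUE	essential
q120	TRUE	FALSE	TRUE	essential
q121	TRUE	FALSE	TRUE	essential
q122	TRUE	FALSE	TRUE	essential
q123	TRUE	FALSE	TRUE	essential
q124	TRUE	FALSE	TRUE	essential
q125	TRUE	FALSE	TRUE	essential
q126	TRUE	FALSE	TRUE	essential
q127	TRUE	FALSE	TRUE	essential
q128	TRUE	FALSE	TRUE	essential
q129	TRUE	FALSE	TRUE	essential
q130	TRUE	FALSE	TRUE	essential
q131	TRUE	FALSE	TRUE	essential
q132	TRUE	FALSE	FALSE	none
q133	TRUE	FALSE	FALSE	none
q134	TRUE	FALSE	FALSE	none
q135	TRUE	FALSE	FALSE	none
q136	TRUE	FALSE	FALSE	none
q137	TRUE	FALSE	FALSE	none
q138	TRUE	FALSE	FALSE	none
q139	TRUE	FALSE	FALSE	none
q140	TRUE	FALSE	FALSE	none
q141	TRUE	FALSE	FALSE	none
q142	TRUE	FALSE	FALSE	none
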