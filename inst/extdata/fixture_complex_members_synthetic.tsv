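# boescan synthetic fixture: 20 complexes: 5 bypassable / 11 non / 4 mixed
# generated by tools/make_fixtures.R (fixed seed)
complex_id	gene_id	queried
cpx01	q008	TRUE
cpx01	q009	TRUE
cpx01	q010	TRUE
cpx01	q011	TRUE
cpx02	q012	TRUE
cpx02	q013	TRUE
cpx02	q014	TRUE
cpx03	q015	TRUE
cpx03	q016	TRUE
cpx03	q017	TRUE
cpx03	q018	TRUE
cpx04	q019	TRUE
cpx04	q020	TRUE
cpx05	q021	TRUE
cpx05	q022	TRUE
cpx06	q039	TRUE
cpx06	q040	TRUE
cpx07	q041	TRUE
cpx07	q042	TRUE
cpx07	q043	TRUE
cpx08	q044	TRUE
cpx08	q045	TRUE
cpx09	q046	TRUE
cpx09	q047	TRUE
cpx09	q048	TRUE
cpx10	q049	TRUE
cpx10	q050	TRUE
cpx10	q051	TRUE
cpx10	q052	TRUE
cpx11	q053	TRUE
cpx11	q054	TRUE
cpx11	q055	TRUE
cpx11	q056	TRUE
cpx12	q057	TRUE
cpx12	q058	TRUE
cpx13	q059	TRUE
cpx13	q060	TRUE
cpx13	q061	TRUE
cpx14	q062	TRUE
cpx14	q063	TRUE
cpx14	q064	TRUE
cpx15	q065	TRUE
cpx15	q066	TRUE
cpx15	q067	TRUE
cpx15	q068	TRUE
cpx16	q069	TRUE
cpx16	q070	TRUE
cpx17	q023	TRUE
cpx17	q071	TRUE
cpx18	q024	TRUE
cpx18	q072	TRUE
cpx18	q073	TRUE
cpx19	q025	TRUE
cpx19	q026	TRUE
cpx19	q074	TRUE
cpx19	q075	TRUE
cpx20	q027	TRUE
cpx20	q028	TRUE
cpx20	q076	TRUE
cpx20	q077	TRUE
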