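gene_id	duplicate_pair_id	copy_count
starch001	dup01	0
starch002	dup01	1
starch003	dup02	1
starch004	dup02	1
starch005	dup03	1
starch006	dup03	1
starch007	dup04	0
starch008	dup04	0
starch009	dup05	2
starch010	dup05	1
starch011	dup06	0
starch012	dup06	0
starch013	dup07	3
starch014	dup07	0
starch015	dup08	0
starch016	dup08	2
starch017	dup09	0
starch018	dup09	2
starch019	dup10	0
starch020	dup10	1
starch021	dup11	1
starch022	dup11	0
starch023	dup12	0
starch024	dup12	1
starch025	dup13	0
starch026	dup13	0
starch027	dup14	1
starch028	dup14	0
starch029	dup15	2
starch030	dup15	0
starch031	dup16	0
starch032	dup16	0
starch033	dup17	1
starch034	dup17	0
starch035	dup18	2
starch036	dup18	1
starch037	dup19	0
starch038	dup19	0
starch039	dup20	0
starch040	dup20	1
starch041	NA	1
starch042	NA	1
starch043	NA	1
starch044	NA	0
starch045	NA	0
starch046	NA	0
starch047	NA	1
starch048	NA	0
starch049	NA	1
starch050	NA	0
starch051	NA	0
starch052	NA	0
starch053	NA	3
starch054	NA	0
starch055	NA	2
starch056	NA	0
starch057	NA	3
starch058	NA	1
starch059	NA	0
starch060	NA	0
starch061	NA	0
starch062	NA	0
starch063	NA	0
starch064	NA	0
starch065	NA	1
starch066	NA	0
starch067	NA	0
starch068	NA	1
starch069	NA	2
starch070	NA	0
starch071	NA	1
starch072	NA	0
starch073	NA	2
starch074	NA	1
starch075	NA	0
starch076	NA	2
starch077	NA	0
starch078	NA	0
starch079	NA	0
starch080	NA	0
starch081	NA	0
starch082	NA	2
starch083	NA	0
starch084	NA	2
starch085	NA	0
starch086	NA	0
starch087	NA	0
starch088	NA	0
starch089	NA	1
starch090	NA	0
starch091	NA	0
starch092	NA	1
starch093	NA	2
starch094	NA	0
starch095	NA	0
starch096	NA	3
starch097	NA	0
starch098	NA	0
starch099	NA	1
starch100	NA	1
starch101	NA	2
starch102	NA	1
starch103	NA	1
starch104	NA	1
starch105	NA	0
starch106	NA	2
starch107	NA	2
starch108	NA	0
starch109	NA	1
starch110	NA	1
starch111	NA	1
starch112	NA	0
starch113	NA	0
starch114	NA	1
starch115	NA	0
starch116	NA	1
starch117	NA	0
starch118	NA	1
starch119	NA	1
starch120	NA	2
starch121	NA	0
starch122	NA	1
starch123	NA	2
starch124	NA	0
starch125	NA	2
starch126	NA	3
starch127	NA	0
starch128	NA	1
starch129	NA	2
starch130	NA	0
starch131	NA	1
starch132	NA	0
starch133	NA	0
starch134	NA	2
starch135	NA	1
starch136	NA	1
starch137	NA	0
starch138	NA	0
starch139	NA	1
starch140	NA	0
starch141	NA	2
starch142	NA	3
starch143	NA	1
starch144	NA	1
starch145	NA	0
starch146	NA	1
starch147	NA	1
starch148	NA	1
starch149	NA	0
starch150	NA	0
starch151	NA	0
starch152	NA	0
starch153	NA	1
starch154	NA	1
starch155	NA	1
starch156	NA	0
starch157	NA	0
starch158	NA	1
starch159	NA	1
starch160	NA	0
starch161	NA	1
starch162	NA	0
starch163	NA	0
starch164	NA	1
starch165	NA	0
starch166	NA	1
starch167	NA	0
starch168	NA	0
starch169	NA	0
starch170	NA	1
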