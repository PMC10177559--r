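symbol	pam50
G001	1
G002	1
G003	1
G004	1
G005	1
G006	1
G007	1
G008	1
G009	1
G010	1
G011	1
G012	1
G013	1
G014	1
G015	1
G016	1
G017	1
G018	1
G019	1
G020	1
G021	1
G022	1
G023	1
G024	1
G025	1
G026	1
G027	1
G028	1
G029	1
G030	1
G031	1
G032	1
G033	1
G034	1
G035	1
G036	1
G037	1
G038	1
G039	1
G040	1
G041	1
G042	1
G043	1
G044	1
G045	1
G046	1
G047	1
G048	1
G049	1
G050	1
G051	0
G052	0
G053	0
G054	0
G055	0
G056	0
G057	0
G058	0
G059	0
G060	0
G061	0
G062	0
G063	0
G064	0
G065	0
G066	0
G067	0
G068	0
G069	0
G070	0
G071	0
G072	0
G073	0
G074	0
G075	0
G076	0
G077	0
G078	0
G079	0
G080	0
G081	0
G082	0
G083	0
G084	0
G085	0
G086	0
G087	0
G088	0
G089	0
G090	0
G091	0
G092	0
G093	0
G094	0
G095	0
G096	0
G097	0
G098	0
G099	0
G100	0
G101	0
G102	0
G103	0
G104	0
G105	0
G106	0
G107	0
G108	0
G109	0
G110	0
G111	0
G112	0
G113	0
G114	0
G115	0
G116	0
G117	0
G118	0
G119	0
G120	0
G121	0
G122	0
G123	0
G124	0
G125	0
G126	0
G127	0
G128	0
G129	0
G130	0
G131	0
G132	0
G133	0
G134	0
G135	0
G136	0
G137	0
G138	0
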