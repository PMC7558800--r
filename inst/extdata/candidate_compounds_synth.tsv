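compound_id	name	herbs	ob	caco2	dl	whitelist
HCC001	sitosterol	CX	49.04	1.025	0.345	FALSE
HCC002	wallichilide	CX;HQ	82.29	-0.293	0.755	FALSE
HCC003	7-O-methylisomucronulatol	HQ	61.53	1.288	0.236	FALSE
HCC004	isoflavanone	CX	32.02	0.629	0.427	FALSE
HCC005	1,7-dihydroxy-3,9-dimethoxy pterocarpene	CX	66.18	0.765	0.437	FALSE
HCC006	3,9-di-O-methylnissolin	JC	68.79	0.936	0.79	FALSE
HCC007	ergotamine	DL	80.98	1.0	0.807	FALSE
HCC008	hederagenin	DL	39.53	0.837	0.601	FALSE
HCC009	isorhamnetin	HQ;CX	42.22	0.719	0.348	FALSE
HCC010	xanthinin	JC	40.25	0.085	0.225	FALSE
HCC011	mairin	DL;CX	84.28	0.636	0.527	FALSE
HCC012	perlolyrine	HQ	85.31	0.688	0.497	FALSE
HCC013	bassianin	JC	92.6	0.674	0.244	FALSE
HCC014	(6aR,11aR)-9,10-dimethoxy-6a,11a-dihydro-6H-benzofurano[3,2-c]chromen-3-ol (73340-41-7)	HQ	64.47	-0.141	0.362	FALSE
HCC015	bifendate	JC	60.1	0.358	0.351	FALSE
HCC016	lupeol acetate	JC	66.8	0.095	0.321	FALSE
HCC017	calycosin	HQ	86.72	1.005	0.226	FALSE
HCC018	kaempferol	DL;HQ	39.96	1.281	0.274	FALSE
HCC019	senkyunone	HQ;DL	67.95	-0.303	0.737	FALSE
HCC020	(3S,8S,9S,10R,13R,14S,17R)-10,13-dimethyl-17-[(2R,5S)-5-propan-2-yloctan-2-yl]-2,3,4,7,8,9,11,12,14,15,16,17-dodecahydro-1H-cyclopenta[a]phenanthren-3-ol (64997-52-0)	HQ	70.15	0.399	0.592	FALSE
HCC021	hyrcanoside	JC	62.79	0.167	0.282	FALSE
HCC022	mandenol	HQ	80.97	0.636	0.338	FALSE
HCC023	4-guanidino-1-butanol	CX	49.3	-0.185	0.257	FALSE
HCC024	cholesteryl ferulate	CX;DL	34.46	0.048	0.663	FALSE
HCC025	(3R)-3-(2-hydroxy-3,4-dimethoxyphenyl)chroman-7-ol (64474-51-7)	DL	44.12	0.383	0.577	FALSE
HCC026	ecdysterone	DL;HQ	45.34	0.598	0.8	FALSE
HCC027	quercetin	DL;CX	30.69	1.383	0.335	FALSE
HCC028	guanosine	CX	49.92	0.116	0.251	FALSE
HCC029	jaranol	JC	31.3	-0.109	0.357	FALSE
HCC030	beauvericin	DL	39.22	1.073	0.65	FALSE
HCC031	myricanone	CX	62.51	0.169	0.616	FALSE
HCC032	formononetin	DL	86.02	-0.104	0.287	FALSE
HCC033	ligustrazine	JC	27.95	0.381	0.091	TRUE
HCC034	senkyunolide H	HQ	24.02	-0.435	0.02	TRUE
HCC035	ononin	JC	17.4	-0.374	0.115	TRUE
HCC036	calycosin 7-O-glucoside	DL	18.55	0.493	0.099	TRUE
HCC037	butylphthalide	HQ	18.15	0.204	0.068	TRUE
HCC038	senkyunolide I	DL	21.94	-0.59	0.037	TRUE
HCC039	senkyunolide A	JC	11.67	-0.823	0.136	TRUE
HCC040	coniferyl ferulate	JC	20.25	-0.947	0.142	TRUE
HCC041	chlorogenic acid	JC	3.11	-0.642	0.084	TRUE
HCC042	astragaloside IV	DL	3.31	-0.174	0.111	TRUE
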