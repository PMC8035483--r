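index	name	abbreviation	class	dmn
1	Left precentral gyrus	PreCG.L	cortical	0
2	Right precentral gyrus	PreCG.R	cortical	0
3	Left superior frontal gyrus, dorsolateral	SFGdor.L	cortical	0
4	Right superior frontal gyrus, dorsolateral	SFGdor.R	cortical	0
5	Left superior frontal gyrus, orbital part	ORBsup.L	cortical	0
6	Right superior frontal gyrus, orbital part	ORBsup.R	cortical	0
7	Left middle frontal gyrus	MFG.L	cortical	0
8	Right middle frontal gyrus	MFG.R	cortical	0
9	Left middle frontal gyrus, orbital part	ORBmid.L	cortical	0
10	Right middle frontal gyrus, orbital part	ORBmid.R	cortical	0
11	Left inferior frontal gyrus, opercular part	IFGoperc.L	cortical	0
12	Right inferior frontal gyrus, opercular part	IFGoperc.R	cortical	0
13	Left inferior frontal gyrus, triangular part	IFGtriang.L	cortical	0
14	Right inferior frontal gyrus, triangular part	IFGtriang.R	cortical	0
15	Left inferior frontal gyrus, orbital part	ORBinf.L	cortical	0
16	Right inferior frontal gyrus, orbital part	ORBinf.R	cortical	0
17	Left rolandic operculum	ROL.L	cortical	0
18	Right rolandic operculum	ROL.R	cortical	0
19	Left supplementary motor area	SMA.L	cortical	0
20	Right supplementary motor area	SMA.R	cortical	0
21	Left olfactory cortex	OLF.L	cortical	0
22	Right olfactory cortex	OLF.R	cortical	0
23	Left superior frontal gyrus, medial	SFGmed.L	cortical	1
24	Right superior frontal gyrus, medial	SFGmed.R	cortical	1
25	Left superior frontal gyrus, medial orbital	ORBsupmed.L	cortical	0
26	Right superior frontal gyrus, medial orbital	ORBsupmed.R	cortical	0
27	Left gyrus rectus	REC.L	cortical	0
28	Right gyrus rectus	REC.R	cortical	0
29	Left insula	INS.L	cortical	0
30	Right insula	INS.R	cortical	0
31	Left anterior cingulate and paracingulate gyri	ACG.L	cortical	0
32	Right anterior cingulate and paracingulate gyri	ACG.R	cortical	0
33	Left median cingulate and paracingulate gyri	DCG.L	cortical	0
34	Right median cingulate and paracingulate gyri	DCG.R	cortical	0
35	Left posterior cingulate gyrus	PCG.L	cortical	1
36	Right posterior cingulate gyrus	PCG.R	cortical	0
37	Left hippocampus	HIP.L	subcortical	0
38	Right hippocampus	HIP.R	subcortical	1
39	Left parahippocampal gyrus	PHG.L	cortical	0
40	Right parahippocampal gyrus	PHG.R	cortical	0
41	Left amygdala	AMYG.L	subcortical	0
42	Right amygdala	AMYG.R	subcortical	1
43	Left calcarine fissure and surrounding cortex	CAL.L	cortical	0
44	Right calcarine fissure and surrounding cortex	CAL.R	cortical	0
45	Left cuneus	CUN.L	cortical	0
46	Right cuneus	CUN.R	cortical	0
47	Left lingual gyrus	LING.L	cortical	0
48	Right lingual gyrus	LING.R	cortical	0
49	Left superior occipital gyrus	SOG.L	cortical	0
50	Right superior occipital gyrus	SOG.R	cortical	0
51	Left middle occipital gyrus	MOG.L	cortical	0
52	Right middle occipital gyrus	MOG.R	cortical	0
53	Left inferior occipital gyrus	IOG.L	cortical	0
54	Right inferior occipital gyrus	IOG.R	cortical	0
55	Left fusiform gyrus	FFG.L	cortical	0
56	Right fusiform gyrus	FFG.R	cortical	0
57	Left postcentral gyrus	PoCG.L	cortical	0
58	Right postcentral gyrus	PoCG.R	cortical	0
59	Left superior parietal gyrus	SPG.L	cortical	0
60	Right superior parietal gyrus	SPG.R	cortical	0
61	Left inferior parietal, but supramarginal and angular gyri	IPL.L	cortical	0
62	Right inferior parietal, but supramarginal and angular gyri	IPL.R	cortical	0
63	Left supramarginal gyrus	SMG.L	cortical	0
64	Right supramarginal gyrus	SMG.R	cortical	0
65	Left angular gyrus	ANG.L	cortical	1
66	Right angular gyrus	ANG.R	cortical	0
67	Left precuneus	PCUN.L	cortical	0
68	Right precuneus	PCUN.R	cortical	1
69	Left paracentral lobule	PCL.L	cortical	0
70	Right paracentral lobule	PCL.R	cortical	0
71	Left caudate nucleus	CAU.L	subcortical	0
72	Right caudate nucleus	CAU.R	subcortical	0
73	Left lenticular nucleus, putamen	PUT.L	subcortical	0
74	Right lenticular nucleus, putamen	PUT.R	subcortical	0
75	Left lenticular nucleus, pallidum	PAL.L	subcortical	0
76	Right lenticular nucleus, pallidum	PAL.R	subcortical	0
77	Left thalamus	THA.L	subcortical	0
78	Right thalamus	THA.R	subcortical	0
79	Left heschl gyrus	HES.L	cortical	0
80	Right heschl gyrus	HES.R	cortical	0
81	Left superior temporal gyrus	STG.L	cortical	0
82	Right superior temporal gyrus	STG.R	cortical	0
83	Left temporal pole: superior temporal gyrus	TPOsup.L	cortical	0
84	Right temporal pole: superior temporal gyrus	TPOsup.R	cortical	0
85	Left middle temporal gyrus	MTG.L	cortical	0
86	Right middle temporal gyrus	MTG.R	cortical	0
87	Left temporal pole: middle temporal gyrus	TPOmid.L	cortical	0
88	Right temporal pole: middle temporal gyrus	TPOmid.R	cortical	0
89	Left inferior temporal gyrus	ITG.L	cortical	0
90	Right inferior temporal gyrus	ITG.R	cortical	0
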