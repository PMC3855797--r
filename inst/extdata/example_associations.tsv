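probe	chr	position	gene	trait	beta	se	p	h2	high_h2
cg13782134	16	67919362	NRN1L	FBS2/FS2	-0.36	0.05	1.19e-9	0.61	yes
cg08392591	16	89556376	ANKRD11	FBGS/(FB+FBG+FBGS)	0.35	0.06	3.05e-8	0.35	no
cg13782134	16	67919362	NRN1L	FBS2/(FS2+FBS2)	-0.33	0.05	5.8e-8	0.61	yes
cg16029957	2	37425956	QPCT	GP13n	-0.19	0.03	2e-7	0.70	yes
cg16029957	2	37425956	QPCT	Bn/(Fn + FBn) ‰	-0.19	0.03	3.57e-7	0.69	yes
cg26991199	1	24307153	SFRS10	GP24	0.24	0.04	8.99e-7		no
cg26991199	1	24307153	SFRS10	FBGS/(FB+FBG+FBGS)	0.28	0.05	1.01e-6	0.35	no
cg16029957	2	37425956	QPCT	GP13	-0.17	0.03	1.44e-6	0.70	yes
cg26991199	1	24307153	SFRS10	GP19	0.27	0.05	1.47e-6	0.27	no
cg08392591	16	89556376	ANKRD11	FBGS/(FBG+FBGS)	0.34	0.07	1.67e-6	0.32	no
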