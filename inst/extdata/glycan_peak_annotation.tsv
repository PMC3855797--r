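peak	structure	fucosylated	bisecting	gal	sial	source
GP1	FA1	1	0	0	0	convention
GP2	A2	0	0	0	0	convention
GP3	A2B	0	1	0	0	convention
GP4	FA2	1	0	0	0	anchor
GP5	FA2B	1	1	0	0	convention
GP6	FA2B	1	1	0	0	convention
GP7	A2G1	0	0	1	0	convention
GP8	FA2G1	1	0	1	0	anchor
GP9	FA2G1	1	0	1	0	anchor
GP10	FA2BG1	1	1	1	0	convention
GP11	FA2BG1	1	1	1	0	convention
GP12	A2G2	0	0	2	0	convention
GP13	A2BG2	0	1	2	0	convention
GP14	FA2G2	1	0	2	0	anchor
GP15	FA2BG2	1	1	2	0	convention
GP16	FA2G1S1	1	0	1	1	convention
GP17	FA2BG1S1	1	1	1	1	convention
GP18	FA2G2S1	1	0	2	1	convention
GP19	FA2BG2S1	1	1	2	1	convention
GP20	A2G2S1	0	0	2	1	convention
GP21	A2G2S2	0	0	2	2	anchor
GP22	A2BG2S2	0	1	2	2	convention
GP23	FA2G2S2	1	0	2	2	convention
GP24	FA2BG2S2	1	1	2	2	convention
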