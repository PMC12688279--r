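rank	circRNA	verified
1	ANXA2	1
2	CALD1	1
3	VIM	1
4	FN1	1
5	HSP90B1	1
6	DCN	0
7	HMGA2	1
8	COL3A1	1
9	EFEMP1	1
10	COL4A2	1
11	FBLN1	1
12	KRT7	1
13	COL6A2	1
14	PKM	1
15	LINC01089	0
16	CTTN	1
17	LTBP3	1
18	MGAT4B	1
19	TGFBI	1
20	HNRNPA2B1	1
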