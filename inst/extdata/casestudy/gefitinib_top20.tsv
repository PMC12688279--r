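rank	circRNA	verified
1	VIM	1
2	CALD1	1
3	COL6A2	1
4	HSP90B1	1
5	FN1	1
6	COL4A1	1
7	ANXA2	1
8	PKM	1
9	MGAT4B	1
10	EFEMP2	0
11	FBLN1	1
12	LINC01089	0
13	KRT7	1
14	CTTN	1
15	TGFBI	1
16	DCN	0
17	COL8A1	0
18	HNRNPA2B1	1
19	LTBP3	1
20	HMGA2	0
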