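rank	circRNA	verified
1	HNRNPA2B1	1
2	CALD1	1
3	VIM	1
4	COL3A1	1
5	LINC01089	0
6	DCN	0
7	HMGA2	1
8	ANXA2	1
9	FN1	1
10	EFEMP1	1
11	COL4A2	1
12	FBLN1	0
13	LTBP3	1
14	KRT7	1
15	CTTN	1
16	COL6A2	1
17	TGFBI	1
18	PKM	0
19	MGAT4B	1
20	COL8A1	0
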