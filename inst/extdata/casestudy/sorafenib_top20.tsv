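rank	circRNA	verified
1	COL3A1	1
2	VIM	1
3	ANXA2	1
4	CALD1	1
5	COL6A2	1
6	FBLN1	1
7	PKM	1
8	LINC01089	0
9	HNRNPA2B1	1
10	EFEMP1	1
11	HSP90B1	1
12	FN1	1
13	KRT7	1
14	LTBP3	1
15	CTTN	1
16	DCBLD2	1
17	HMGA2	0
18	MGAT4B	1
19	COL8A1	0
20	COL4A2	0
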