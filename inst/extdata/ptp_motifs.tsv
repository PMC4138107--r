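motif_id	name	role	active_pattern	relaxed_pattern	offset	tolerance	template_seq
1	KNRY loop	active_site	[KR].{0,2}R.?[YF]	[KR].{0,2}R	-170	50	NLNKNRY
2	Motif 2 (core, beta-sheet N)	core	DYINA[ST]	DYINA[ST]	-145	30	DYINAS
3	Motif 3 (core)	core	EFW[RK]M[VIL]	EFW[RK]M[VIL]	-115	30	EFWRMV
4	Motif 4 (core)	core	GP[LM]P[NS]T	GP[LM]P[NS]T	-90	30	GPLPNT
5	Motif 5 (core)	core	NRV[ML]E[KR]	NRV[ML]E[KR]	-70	25	NRVMEK
6	Motif 6 (core, pre P-loop)	core	GSL[KR]PG	GSL[KR]PG	-15	12	GSLKPG
7	Motif 7 (core, alpha-helical C)	core	SPEHG[VI]	SPEHG[VI]	20	15	SPEHGV
8	WPD loop	active_site	WPD	(WP|W.D)	-42	18	YTTWPDFGIP
9	P-loop/HCX5R	active_site	HCSAG[IVLM]GR	(H..AG.G|C.{5}R)	-4	12	PIIHCSAGIGRSGT
10	Q loop	active_site	.Q.{3}Q.{3}	Q.{0,2}[YF]	50	20	IQTVDQLYF
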