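accession	gene_id	domain_index	boundary_start	boundary_end	presence	m1_seq	m8_seq	m9_seq	m10_seq	m1_status	m8_status	m9_status	m10_status	domain_verdict
AAEL001046	AAEL001046	1	1	182	DEGENERATE					ABSENT	ABSENT	ABSENT	ABSENT	INACTIVE
AAEL001046	AAEL001046	2	189	281	DEGENERATE					ABSENT	ABSENT	ABSENT	ABSENT	INACTIVE
AAEL001919-PA	AAEL001919	1	1	206	WELL_FORMED		YTTWPDFGIP	PIIHCSAGIGRSGT	IQTVDQLYF	ABSENT	ACTIVE	ACTIVE	ACTIVE	ACTIVE
AAEL001919-PB	AAEL001919	1	1	206	WELL_FORMED		YTTWPDFGIP	PIIHCSAGIGRSGT	IQTVDQLYF	ABSENT	ACTIVE	ACTIVE	ACTIVE	ACTIVE
AAEL003108	AAEL003108	1	603	979	WELL_FORMED	NLNKNRY	YLAWPDHGVP	PIIHCSAGIGRTG	VQNVSQYRF	ACTIVE	ACTIVE	ACTIVE	ACTIVE	ACTIVE
AAEL005492	AAEL005492	1	410	681	WELL_FORMED	NLAKNRY	FTSWPDYGVP	PMVVHCSAGIGRT	IQMPDQYVF	ACTIVE	ACTIVE	ACTIVE	ACTIVE	ACTIVE
AAEL008528-PA	AAEL008528	1	103	167	DEGENERATE					ABSENT	ABSENT	ABSENT	ABSENT	INACTIVE
AAEL008528-PA	AAEL008528	2	205	445	WELL_FORMED	NESKHKR	FQVWPDHGVP	PICVHCSAGIGRT	VQTEAQYKF	INACTIVE	ACTIVE	ACTIVE	ACTIVE	ACTIVE
AAEL008528-PB	AAEL008528	1	103	167	DEGENERATE					ABSENT	ABSENT	ABSENT	ABSENT	INACTIVE
AAEL008528-PB	AAEL008528	2	205	445	WELL_FORMED	NESKHKR	FQVWPDHGVP	PICVHCSAGIGRT	VQTEAQYKF	INACTIVE	ACTIVE	ACTIVE	ACTIVE	ACTIVE
AAEL010234	AAEL010234	1	991	1228	WELL_FORMED	NKARNF	YNEWGDQNCP	PPVLIHCNEGGGRT	TPSLAQYKF	ACTIVE	INACTIVE	INACTIVE	INACTIVE	INACTIVE
AAEL010914	AAEL010914	1	307	573	WELL_FORMED	KNRSID	LWPKQSA	NCLNGSDRSC	DPNHMQL	INACTIVE	INACTIVE	INACTIVE	INACTIVE	INACTIVE
AAEL011434	AAEL011434	1	781	1181	WELL_FORMED	QSKNRY	FPDWPDHRSP	PIIHCSAGIGRTG	VQNSEQYEL	ACTIVE	ACTIVE	ACTIVE	ACTIVE	ACTIVE
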