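gene_id	reason
AAEL011434	Ortholog of a MAPK-pathway dual-specificity phosphatase; curated out of the classical PTP group
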