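term	protein_type
adenylate cyclase	Adenylate Cyclase
subunit	G-protein subunits
receptor kinase	GRK
cAMP-dependent protein kinase	PKA
GTPase	GTPase
GTPase activating protein	GAP
GAP	GAP
exchange factor	GEF
GEF	GEF
Rho	GTPase and GAP
Ras	GTPase
GTP-binding	GTPase and GAP
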