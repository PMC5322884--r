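G-protein coupled receptor activity, unknown ligand
Mas proto-oncogene receptor activity
Orphan G protein coupled receptor activity
Orphan GPCR activity
RDC1 receptor activity
Super conserved receptor expressed in brain receptor activity
Epstein-Barr Virus-induced receptor activity
SREB receptor
EBV-induced receptor
Orphan G-protein coupled receptor activity
Receptor activity, G-protein coupled
G protein coupled receptor activity
G protein linked receptor activity
GPCR activity
Ligand-dependent GPCR activity
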