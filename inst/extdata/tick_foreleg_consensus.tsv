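orf_id	pred_by	pca_class	pca_subfamily	gpcrpred_class	gpcrpred_subfamily
athaller1048_233(length)_-1(strand)_0(frame)	TGP	A	(Rhod)opsin	A	Rhodopsin
athaller1218_287(length)_1(strand)_2(frame)	TGP	A	(Rhod)opsin	A	Rhodopsin
athaller1386_405(length)_1(strand)_0(frame)	TGP	A	(Rhod)opsin	A	Prostanoid
athaller1516_468(length)_-1(strand)_0(frame)	TGP	A	(Rhod)opsin	A	Amine
athaller1962_286(length)_1(strand)_0(frame)	TGP	A	(Rhod)opsin	A	Rhodopsin
athaller2143_275(length)_1(strand)_0(frame)	TGP	A	(Rhod)opsin	A	Peptide
athaller2185_273(length)_-1(strand)_2(frame)	TGP	A	(Rhod)opsin	A	Rhodopsin
athaller2570_238(length)_-1(strand)_0(frame)	TGP	A	(Rhod)opsin	A	Peptide
athaller779_250(length)_1(strand)_1(frame)	TGP	A	(Rhod)opsin	A	Rhodopsin
athaller1702_381(length)_-1(strand)_2(frame)	TGP	A	Amine	A	Peptide
athaller1768_231(length)_-1(strand)_2(frame)	TGP	A	Amine	A	Peptide
athaller1154_282(length)_1(strand)_0(frame)	TGP	A	Melatonin	A	Peptide
athaller1479_188(length)_1(strand)_2(frame)	TGP	A	Melatonin	A	Peptide
athaller3002_157(length)_-1(strand)_1(frame)	TGP	A	Melatonin	A	Peptide
athaller1138_187(length)_1(strand)_2(frame)	TGP	A	NucleotideLike	A	Amine
athaller1414_324(length)_-1(strand)_2(frame)	TGP	A	NucleotideLike	A	Amine
athaller1735_320(length)_-1(strand)_1(frame)	TGP	A	NucleotideLike	A	Peptide
athaller1975_264(length)_1(strand)_0(frame)	TGP	A	NucleotideLike	A	Peptide
athaller2639_255(length)_1(strand)_2(frame)	TGP	A	NucleotideLike	A	Peptide
athaller1224_421(length)_1(strand)_0(frame)	AGP	A	Peptide	A	Peptide
athaller3668_184(length)_-1(strand)_1(frame)	TGP	A	Olfactory	A	Peptide
athaller3787_156(length)_1(strand)_0(frame)	TAP	A	Olfactory	NA	-
athaller536_258(length)_-1(strand)_2(frame)	TGP	A	Olfactory	A	Olfactory
athaller537_251(length)_-1(strand)_2(frame)	TGP	A	Olfactory	A	Olfactory
athaller1342_403(length)_-1(strand)_0(frame)	TGP	A	Orphan	A	Rhodopsin
athaller1823_379(length)_1(strand)_2(frame)	TGP	A	Orphan	A	Rhodopsin
athaller2698_229(length)_-1(strand)_1(frame)	TGP	A	Orphan	A	Rhodopsin
athaller356_291(length)_1(strand)_1(frame)	TAP	A	Orphan	NA	-
athaller454_222(length)_1(strand)_0(frame)	TGP	A	Orphan	A	Peptide
athaller1140_442(length)_-1(strand)_0(frame)	TGP	A	Peptide	A	Peptide
athaller1303_323(length)_-1(strand)_0(frame)	TGP	A	Peptide	A	Rhodopsin
athaller1377_284(length)_1(strand)_0(frame)	TGP	A	Peptide	A	Rhodopsin
athaller1425_272(length)_-1(strand)_2(frame)	TGP	A	Peptide	A	Peptide
athaller1599_264(length)_1(strand)_0(frame)	TGP	A	Peptide	A	Peptide
athaller1917_323(length)_-1(strand)_0(frame)	TGP	A	Peptide	A	Peptide
athaller1927_354(length)_-1(strand)_2(frame)	TGP	A	Peptide	A	Nucleotide-like
athaller2082_326(length)_-1(strand)_0(frame)	TGP	A	Peptide	A	Peptide
athaller2362_275(length)_-1(strand)_0(frame)	TGP	A	Peptide	A	Peptide
athaller238_313(length)_-1(strand)_2(frame)	TGP	A	Peptide	A	Peptide
athaller239_313(length)_-1(strand)_2(frame)	TGP	A	Peptide	A	Peptide
athaller482_285(length)_1(strand)_2(frame)	TGP	A	Peptide	A	Peptide
athaller483_285(length)_1(strand)_2(frame)	TGP	A	Peptide	A	Peptide
athaller1230_465(length)_-1(strand)_0(frame)	AGP	B	Brainspecific angiogenesis inhibitor (BAI)	B	-
athaller552_430(length)_1(strand)_0(frame)	TGP	B	GPR133	A	Amine
athaller1160_759(length)_1(strand)_1(frame)	TGP	C	GABAB	A	Amine
athaller1175_662(length)_1(strand)_1(frame)	TAGP	C	GABAB	C	-
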