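orf_id	blastx_uniref	blastp_turticae	blastp_chelicerates	blastp_synganglion	blastp_iscapularis	pfam
athaller3876_117(length)_1(strand)_1(frame)				x
athaller1224_421(length)_1(strand)_0(frame)				x
athaller3802_175(length)_1(strand)_2(frame)				x
athaller3787_156(length)_1(strand)_0(frame)				x
athaller1175_662(length)_1(strand)_1(frame)			x		x	x
athaller1230_465(length)_-1(strand)_0(frame)					x
athaller2715_233(length)_1(strand)_2(frame)		x	x		x
athaller2824_126(length)_1(strand)_1(frame)					x
athaller356_291(length)_1(strand)_1(frame)	x				x	x
athaller357_301(length)_1(strand)_2(frame)	x					x
athaller4258_129(length)_-1(strand)_2(frame)		x	x		x
athaller4697_102(length)_1(strand)_0(frame)			x		x	x
athaller675_193(length)_1(strand)_0(frame)					x
athaller2474_190(length)_1(strand)_1(frame)	x					x
athaller4147_161(length)_-1(strand)_2(frame)	x					x
athaller1305_187(length)_-1(strand)_1(frame)		x	x
athaller1897_360(length)_-1(strand)_2(frame)		x	x
athaller508_240(length)_-1(strand)_1(frame)		x	x
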