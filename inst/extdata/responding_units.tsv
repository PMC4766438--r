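unit_id	sensillum	osn	receptors	glomerulus
Or67d	at1	at1A	Or67d	DA1
Or83c	at2	at2A	Or83c	DC3
Or23a	at2	at2B	Or23a	DA3
Or19a	at3	at3A	Or19a, Or19b	DC1
Or2a	at3	at3	Or2a	DA4m
Or43a	at3	at3	Or43a	DA4l
Or47b	at4	at4A	Or47b	VA1v
Or65a	at4	at4B	Or65a, Or65b, Or65c	DL3
Or88a	at4	at4C	Or88a	VA1d
Or42b	ab1	ab1A	Or42b	DM1
Or92a	ab1	ab1B	Or92a	VA2
Gr21a.Gr63a	ab1	ab1C	Gr21a, Gr63a	V
Or10a	ab1	ab1D	Or10a, Gr10a	DL1
Or59b	ab2	ab2A	Or59b	DM4
ab2B	ab2	ab2B	Or33b, Or85a	DM5
Or85a	ab2	ab2B	Or85a	DM5
Or22a	ab3	ab3A	Or22a, Or22b	DM2
Or85b	ab3	ab3B	Or85b	VM5d
Or7a	ab4	ab4A	Or7a	DL5
ab4B	ab4	ab4B	Or33a, Or56a	DA2
Or33a	ab4	ab4B	Or33a	DA2
Or56a	ab4	ab4B	Or56a	DA2
Or82a	ab5	ab5A	Or82a	VA6
ab5B	ab5	ab5B	Or33b, Or47a	DM3
Or33b	ab5	ab5B	Or33b	DM3
Or47a	ab5	ab5B	Or47a	DM3
Or13a	ab6	ab6A	Or13a	DC2
Or49b	ab6	ab6B	Or49b	VA5
Or98a	ab7	ab7A	Or98a	VM5v
Or67c	ab7	ab7B	Or67c	VC4
Or43b	ab8	ab8A	Or43b	VM2
Or9a	ab8	ab8B	Or9a	VM3
Or67b	ab9	ab9	Or67b	VA3
Or69a	ab9	ab9	Or69aA, Or69aB	D
Or67a	ab10	ab10A	Or67a	DM6
Or49a	ab10	ab10B	Or49a	DL4
Or85f	ab10	ab10B	Or85f	DL4
Ir31a	ac1	ac1	Ir31a	VL2p
Ir75d	ac1	ac1	Ir75d	VL1
Ir92a	ac1	ac1	Ir92a	VM1
Ir75a	ac2	ac2	Ir75a	DP1l
Ir41a	ac2	ac2	Ir41a	VC5
ac3A	ac3	ac3A	Ir75a, Ir75b, Ir75c	DL2d/v
ac3B	ac3	ac3B	Or35a	VC3
Or35a	ac3	ac3B	Or35a	VC3
Ir84a	ac4	ac4	Ir84a	VL2a
Ir76a	ac4	ac4	Ir76a	VM4
Ir64a.DC4	sacIII	sacIII	Ir64a	DC4
Ir64a.DP1m	sacIII	sacIII	Ir64a	DP1m
Or42a	pb1	pb1A	Or42a	VM7d
Or71a	pb1	pb1B	Or71a	VC2
pb2A	pb2	pb2A	Or33c, Or85e	VC1
Or33c	pb2	pb2A	Or33c	VC1
Or85e	pb2	pb2A	Or85e	VC1
Or46a	pb2	pb2B	Or46a	VA7l
Or59c	pb3	pb3A	Or59c	VM7v
Or85d	pb3	pb3B	Or85d	VA4
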