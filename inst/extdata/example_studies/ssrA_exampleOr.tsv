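InChIKey	Name	CAS	CID	SMILES	Response
MLFHJEHSLIIPHL-UHFFFAOYSA-N	isopentyl acetate	NA	NA	NA	45
SHZIWNPUGXLXDT-UHFFFAOYSA-N	ethyl hexanoate	NA	NA	NA	60
CATSNJVOTSVZJV-UHFFFAOYSA-N	2-heptanone	NA	NA	NA	28
ZSIAUFGUXNUGDI-UHFFFAOYSA-N	1-hexanol	NA	NA	NA	18
QTBSBXVTEAMEQO-UHFFFAOYSA-N	acetic acid	NA	NA	NA	5
KXKVLQRXCPHEJC-UHFFFAOYSA-N	methyl acetate	NA	NA	NA	22
JLPUXFOGCDVKGO-GRYCIOLGSA-N	geosmin	NA	NA	NA	2
PGMYKACGEOXYJE-UHFFFAOYSA-N	pentyl acetate	NA	NA	NA	38
SFR	NA	NA	NA	NA	12
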