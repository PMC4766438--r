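InChIKey	Name	CAS	CID	SMILES	Response
CATSNJVOTSVZJV-UHFFFAOYSA-N	2-heptanone	NA	NA	NA	9.0
ZSIAUFGUXNUGDI-UHFFFAOYSA-N	1-hexanol	NA	NA	NA	5.5
QTBSBXVTEAMEQO-UHFFFAOYSA-N	acetic acid	NA	NA	NA	1.2
KXKVLQRXCPHEJC-UHFFFAOYSA-N	methyl acetate	NA	NA	NA	7.0
JLPUXFOGCDVKGO-GRYCIOLGSA-N	geosmin	NA	NA	NA	0.3
PGMYKACGEOXYJE-UHFFFAOYSA-N	pentyl acetate	NA	NA	NA	12.0
OBNCKNCVKJNDBV-UHFFFAOYSA-N	ethyl butyrate	NA	NA	NA	10.5
VSMOENVRRABVKN-UHFFFAOYSA-N	1-octen-3-ol	NA	NA	NA	3.0
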