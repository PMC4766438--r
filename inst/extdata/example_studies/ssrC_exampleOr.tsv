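InChIKey	Name	CAS	CID	SMILES	Response
MLFHJEHSLIIPHL-UHFFFAOYSA-N	isopentyl acetate	NA	NA	NA	30
SHZIWNPUGXLXDT-UHFFFAOYSA-N	ethyl hexanoate	NA	NA	NA	39
CATSNJVOTSVZJV-UHFFFAOYSA-N	2-heptanone	NA	NA	NA	20
QTBSBXVTEAMEQO-UHFFFAOYSA-N	acetic acid	NA	NA	NA	6
JLPUXFOGCDVKGO-GRYCIOLGSA-N	geosmin	NA	NA	NA	3
PGMYKACGEOXYJE-UHFFFAOYSA-N	pentyl acetate	NA	NA	NA	26
OBNCKNCVKJNDBV-UHFFFAOYSA-N	ethyl butyrate	NA	NA	NA	23
VSMOENVRRABVKN-UHFFFAOYSA-N	1-octen-3-ol	NA	NA	NA	9
SFR	NA	NA	NA	NA	8
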