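inchikey	name
MLFHJEHSLIIPHL-UHFFFAOYSA-N	isopentyl acetate
CRDAMVZIKSXKFV-UHFFFAOYSA-N	farnesol
AMQJEAYHLZJPGS-UHFFFAOYSA-N	1-pentanol
QEBNYNLSCGVZOH-UHFFFAOYSA-N	valencene
ROWKJAVDOGWPAT-UHFFFAOYSA-N	3-hydroxy-2-butanone
ZSIAUFGUXNUGDI-UHFFFAOYSA-N	1-hexanol
ULDHMXUKGWMISQ-VIFPVBQESA-N	(S)-(+)-carvone
RWRDLPDLKQPQOW-UHFFFAOYSA-N	pyrrolidine
PFCHFHIRKBAQGU-UHFFFAOYSA-N	3-hexanone
QSJXEFYPDANLFS-UHFFFAOYSA-N	2,3-butanedione
CURLTUGMZLYLDI-UHFFFAOYSA-N	carbon dioxide
OSWPMRLSEDHDFF-UHFFFAOYSA-N	methyl salicylate
KXKVLQRXCPHEJC-UHFFFAOYSA-N	methyl acetate
OMSUIQOIVADKIM-UHFFFAOYSA-N	ethyl 3-hydroxybutyrate
FKRCODPIKNYEAC-UHFFFAOYSA-N	ethyl propionate
SHZIWNPUGXLXDT-UHFFFAOYSA-N	ethyl hexanoate
DKPFZGUDAPQIHT-UHFFFAOYSA-N	butyl acetate
MBDOYVRWFFCFHM-SNAWJCMRSA-N	E2-hexenal
JLPUXFOGCDVKGO-GRYCIOLGSA-N	geosmin
CATSNJVOTSVZJV-UHFFFAOYSA-N	2-heptanone
HIGQPQRQIQDZMP-DHZHZOJOSA-N	geranyl acetate
PGMYKACGEOXYJE-UHFFFAOYSA-N	pentyl acetate
VSMOENVRRABVKN-UHFFFAOYSA-N	1-octen-3-ol
QWVGKYWNOKOFNN-UHFFFAOYSA-N	2-methylphenol
MTZQAGJQAFMTAQ-UHFFFAOYSA-N	ethyl benzoate
LZCLXQDLBQLTDK-UHFFFAOYSA-N	ethyl lactate
ZFDIRQKJPRINOQ-HWKANZROSA-N	ethyl trans-2-butenoate
KWOLFJPFCHCOCG-UHFFFAOYSA-N	acetophenone
LYRIITRHDCNUHV-UHFFFAOYSA-N	ethyl 3-hydroxyhexanoate
BTMVHUNTONAYDX-UHFFFAOYSA-N	butyl propanoate
KDVFRMMRZOCFLS-UHFFFAOYSA-N	2-oxovaleric acid
ROSDSFDQCJNGOL-UHFFFAOYSA-N	dimethylamine
QTBSBXVTEAMEQO-UHFFFAOYSA-N	acetic acid
KIDHWZJUCRJVML-UHFFFAOYSA-N	putrescine
NBBJYMSMWIIQGU-UHFFFAOYSA-N	propanal
BHHGXPLMPWCGHP-UHFFFAOYSA-N	2-phenylethylamine
BBMCTIGTTCKYKF-UHFFFAOYSA-N	1-heptanol
DTUQWGWMVIHBKE-UHFFFAOYSA-N	phenylacetaldehyde
VHUUQVKOLVNVRT-UHFFFAOYSA-N	ammonium hydroxide
OWBTYPJTUOEWEK-UHFFFAOYSA-N	2,3-butanediol
YKYONYBAUNKHLG-UHFFFAOYSA-N	propyl acetate
CHWNEIVBYREQRF-UHFFFAOYSA-N	4-ethylguaiacol
JHIVVAPYMSGYDF-UHFFFAOYSA-N	cyclohexanone
LHXDLQBQYFFVNW-OIBJUYFYSA-N	(1R)-(-)-fenchone
IWDCLRJOBJJRNH-UHFFFAOYSA-N	4-methylphenol
OBNCKNCVKJNDBV-UHFFFAOYSA-N	ethyl butyrate
ICMAFTSLXCXHRK-UHFFFAOYSA-N	ethyl pentanoate
QNVRIHYSUZMSGM-UHFFFAOYSA-N	2-hexanol
GWYFCOCPABKNJV-UHFFFAOYSA-N	isopentanoic acid
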