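species	abbrev	common_name	accession	group	base_weight
Homo sapiens	Hom sap	human	NT_011512.1	primates	11
Pan troglodytes	Pan tro	chimpanzee	NT_106996.1	primates	11
Gorilla gorilla	Gor gor	western gorilla	gorGor3.1:21	primates	10
Pongo pygmaeus	Pon pyg	Bornean orangutan	NW_002891078.1	primates	10
Nomascus leucogenys	Nom leu	northern white-cheeked gibbon	NW_003501402	primates	7
Macaca mulatta	Mac mul	rhesus monkey	NW_001114168.1	primates	7
Callithrix jacchus	Cal jac	common marmoset	NW_003184659	primates	6
Tarsius syrichta	Tar syr	Philippine tarsier	ABRT010367312	primates	5
Otolemur garnettii	Oto gar	greater galago	OtoGar3:GL873528.1	primates	4
Cavia porcellus	Cav por	guinea pig	NT_176367	glires	10
Octodon degus	Oct deg	common degu	AJSA01048215	glires	10
Heterocephalus glaber	Het gla	naked mole rat	AFSB01163805	glires	6
Ictidomys tridecemlineatus	Ict tri	thirteen-lined ground squirrel	AAQQ01741479	glires	9
Mus musculus	Mus mus	house mouse	NT_039625.8	glires	9
Rattus norvegicus	Rat nor	Norway rat	NW_047354	glires	8
Dipodomys ordii	Dip ord	Ord's kangaroo rat	ABRO01075802	glires	6
Oryctolagus cuniculus	Ory cun	European rabbit	NW_003159292	glires	5
Ochotona princeps	Och pri	American pika	AAYZ01049311	glires	5
Bos primigenius taurus	Bos pri t	cow	NW_003103795.1	laurasiatheria	12
Bos primigenius indicus	Bos pri i	zebu	AGFL01000631	laurasiatheria	12
Tursiops truncatus	Tur tru	bottlenose dolphin	ABRN02546477	laurasiatheria	7
Sus scrofa	Sus scr	pig	NW_003611878	laurasiatheria	6
Ailuropoda melanoleuca	Ail mel	giant panda	NW_003217675	laurasiatheria	8
Mustela puturius furo	Mus put f	domestic ferret	AEYP01042946	laurasiatheria	8
Canis lupus familiaris	Can lup f	dog	NW_003726114	laurasiatheria	7
Pteropus vampyrus	Pte vam	flying fox	ABRP01159960	laurasiatheria	4
Condylura cristata	Con cry	star-nosed mole	AJFV01010076	laurasiatheria	3
Loxodonta africanus	Lox afr	African elephant	NW_003573433.1	atlantogenata	4
Procavia capensis	Pro cap	rock hyrax	ABRQ01094447	atlantogenata	4
Echinops telfairi	Ech tel	lesser hedgehog tenrec	AAIY01071949	atlantogenata	3
Choloepus hoffmanni	Cho hof	Hoffman's two-toed sloth	ABVD01435293	atlantogenata	3
Dasypus novemcinctus	Das nov	nine-banded armadillo	AAGV03159065	atlantogenata	3
Macropus eugenii	Mac eug	Tammar wallaby	ABQO020034033	marsupials	2
Sarcophilus harrisii	Sar har	Tasmanian devil	AEFK01137980	marsupials	2
Mondelphis domestica	Mon dom	gray short-tailed opossum	NW_001581956.1	marsupials	1
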