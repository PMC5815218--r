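country	iso2	un_region	inferred_category
United Kingdom	GB	Northern Europe	European
Ireland	IE	Northern Europe	European
France	FR	Western Europe	European
Germany	DE	Western Europe	European
Netherlands	NL	Western Europe	European
Belgium	BE	Western Europe	European
Switzerland	CH	Western Europe	European
Austria	AT	Western Europe	European
Spain	ES	Southern Europe	European
Portugal	PT	Southern Europe	European
Italy	IT	Southern Europe	European
Greece	GR	Southern Europe	European
Sweden	SE	Northern Europe	European
Norway	NO	Northern Europe	European
Denmark	DK	Northern Europe	European
Finland	FI	Northern Europe	European
Iceland	IS	Northern Europe	European
Estonia	EE	Northern Europe	European
Latvia	LV	Northern Europe	European
Lithuania	LT	Northern Europe	European
Poland	PL	Eastern Europe	European
Czechia	CZ	Eastern Europe	European
Hungary	HU	Eastern Europe	European
Romania	RO	Eastern Europe	European
Bulgaria	BG	Eastern Europe	European
Croatia	HR	Southern Europe	European
Ukraine	UA	Eastern Europe	European
Russia	RU	Eastern Europe	Other
China	CN	Eastern Asia	East Asian
Japan	JP	Eastern Asia	East Asian
South Korea	KR	Eastern Asia	East Asian
Taiwan	TW	Eastern Asia	East Asian
Hong Kong	HK	Eastern Asia	East Asian
Mongolia	MN	Eastern Asia	East Asian
India	IN	Southern Asia	South Asian
Pakistan	PK	Southern Asia	South Asian
Bangladesh	BD	Southern Asia	South Asian
Sri Lanka	LK	Southern Asia	South Asian
Nepal	NP	Southern Asia	South Asian
Thailand	TH	South-eastern Asia	South East Asian
Vietnam	VN	South-eastern Asia	South East Asian
Malaysia	MY	South-eastern Asia	South East Asian
Indonesia	ID	South-eastern Asia	South East Asian
Philippines	PH	South-eastern Asia	South East Asian
Singapore	SG	South-eastern Asia	Not reported
Kazakhstan	KZ	Central Asia	Central Asian
Uzbekistan	UZ	Central Asia	Central Asian
Iran	IR	Southern Asia	Greater Middle Eastern (Middle Eastern, North African, or Persian)
Saudi Arabia	SA	Western Asia	Greater Middle Eastern (Middle Eastern, North African, or Persian)
United Arab Emirates	AE	Western Asia	Greater Middle Eastern (Middle Eastern, North African, or Persian)
Israel	IL	Western Asia	Greater Middle Eastern (Middle Eastern, North African, or Persian)
Turkey	TR	Western Asia	Greater Middle Eastern (Middle Eastern, North African, or Persian)
Jordan	JO	Western Asia	Greater Middle Eastern (Middle Eastern, North African, or Persian)
Lebanon	LB	Western Asia	Greater Middle Eastern (Middle Eastern, North African, or Persian)
Egypt	EG	Northern Africa	Greater Middle Eastern (Middle Eastern, North African, or Persian)
Tunisia	TN	Northern Africa	Greater Middle Eastern (Middle Eastern, North African, or Persian)
Morocco	MA	Northern Africa	Greater Middle Eastern (Middle Eastern, North African, or Persian)
Nigeria	NG	Western Africa	Sub-Saharan African
Ghana	GH	Western Africa	Sub-Saharan African
Gambia	GM	Western Africa	Sub-Saharan African
Mali	ML	Western Africa	Sub-Saharan African
Senegal	SN	Western Africa	Sub-Saharan African
Kenya	KE	Eastern Africa	Sub-Saharan African
Uganda	UG	Eastern Africa	Sub-Saharan African
Tanzania	TZ	Eastern Africa	Sub-Saharan African
Ethiopia	ET	Eastern Africa	Sub-Saharan African
Cameroon	CM	Middle Africa	Sub-Saharan African
Malawi	MW	Eastern Africa	Sub-Saharan African
Zambia	ZM	Eastern Africa	Sub-Saharan African
Zimbabwe	ZW	Eastern Africa	Sub-Saharan African
Botswana	BW	Southern Africa	Sub-Saharan African
Mexico	MX	Central America	Hispanic or Latin American
Brazil	BR	South America	Hispanic or Latin American
Colombia	CO	South America	Hispanic or Latin American
Peru	PE	South America	Hispanic or Latin American
Chile	CL	South America	Hispanic or Latin American
Argentina	AR	South America	Hispanic or Latin American
Ecuador	EC	South America	Hispanic or Latin American
Bolivia	BO	South America	Hispanic or Latin American
Venezuela	VE	South America	Hispanic or Latin American
Uruguay	UY	South America	Hispanic or Latin American
Guatemala	GT	Central America	Hispanic or Latin American
Costa Rica	CR	Central America	Hispanic or Latin American
Puerto Rico	PR	Caribbean	Hispanic or Latin American
Barbados	BB	Caribbean	African American or Afro-Caribbean
Jamaica	JM	Caribbean	African American or Afro-Caribbean
Fiji	FJ	Melanesia	Oceanian
Papua New Guinea	PG	Melanesia	Oceanian
Solomon Islands	SB	Melanesia	Oceanian
Samoa	WS	Polynesia	Oceanian
Australia	AU	Australia and New Zealand	Not reported
New Zealand	NZ	Australia and New Zealand	Not reported
United States	US	Northern America	Not reported
Canada	CA	Northern America	Not reported
South Africa	ZA	Southern Africa	Not reported
Suriname	SR	South America	Not reported
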