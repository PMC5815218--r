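name	parent	admixed	synonyms	reference_populations	example_descriptors	definition
Aboriginal Australian		FALSE	Australian Aboriginal		Martu Australian Aboriginal	Individuals who self-report or have been described as Australian Aboriginal, descendants of the early human migration into Australia from Eastern Asia, distinguishable from other Asian populations by mtDNA and Y chromosome variation.
African American or Afro-Caribbean	African	TRUE	African American|Afro-Caribbean|African Caribbean	ACB|ASW	African American|African Caribbean	Individuals who self-report or have been described as African American or Afro-Caribbean, or who genetically cluster with reference populations from this region (ACB, ASW). Significant admixture with European ancestry populations is expected.
African unspecified	African	FALSE	African		African|non-Hispanic black	Individuals described as African without sufficient information to allow classification as African American, Afro-Caribbean or Sub-Saharan African.
Asian unspecified	Asian	FALSE	Asian		Asian|Asian American	Individuals described as Asian without sufficient information to allow classification as East Asian, Central Asian, South Asian or South-East Asian.
Central Asian	Asian	FALSE			Silk Road	Individuals who self-report or have been described as Central Asian. No suitable reference population is currently available for this grouping.
East Asian	Asian	FALSE		CDX|CHB|CHS|JPT	Chinese|Japanese|Korean	Individuals who self-report or have been described as East Asian or one of the sub-populations from this region, or who genetically cluster with reference populations from this region (CDX, CHB, CHS, JPT).
European		FALSE	Caucasian|white	CEU|FIN|GBR|IBS|TSI	Spanish|Swedish|Dutch	Individuals who self-report or have been described as European, Caucasian, white, or one of the sub-populations from this region, or who genetically cluster with reference populations from this region (CEU, FIN, GBR, IBS, TSI).
Greater Middle Eastern (Middle Eastern, North African, or Persian)		FALSE	Greater Middle Eastern|Middle Eastern|North African|Persian		Tunisian|Arab|Iranian	Individuals who self-report or have been described as Middle Eastern, North African, Persian, or one of the sub-populations from this region. The grouping is heterogeneous, with varying degrees of admixture and genetic isolation, and no suitable reference population is currently available.
Hispanic or Latin American		TRUE	Hispanic|Latino|Latin American	CLM|MXL|PEL|PUR	Brazilian|Mexican	Individuals who self-report or have been described as Hispanic, Latino, Latin American, or one of the sub-populations from this region, with known admixture of primarily European, African and Native American ancestries, or who genetically cluster with reference populations from this region (CLM, MXL, PEL, PUR).
Native American		FALSE	Amerindian|American Indian		Pima Indian|Plains American Indian	Indigenous individuals of North, Central and South America, descended from the original human migration into the Americas from Siberia. No suitable reference population is currently available.
Not reported		FALSE				Individuals for which no ancestry or country of recruitment information is available.
Oceanian		FALSE			Solomon Islander|Micronesian	Individuals who self-report or have been described as Oceanian or one of the sub-populations from this region (e.g. Native Hawaiian). No suitable reference population is currently available.
Other		FALSE			Surinamese|Russian	Individuals for whom an ancestry descriptor is known but insufficient information is available to allow assignment to one of the other categories.
Other admixed ancestry		TRUE	other admixed ancestries			Individuals who self-report or have been described as admixed and do not fit the definition of the other admixed categories (African American or Afro-Caribbean; Hispanic or Latin American).
South Asian	Asian	FALSE		BEB|GIH|ITU|PJL|STU	Bangladeshi|Sri Lankan Sinhalese	Individuals who self-report or have been described as South Asian or one of the sub-populations from this region (e.g. Asian Indian), or who genetically cluster with reference populations from this region (BEB, GIH, ITU, PJL, STU).
South East Asian	Asian	FALSE	South-East Asian	KHV	Thai|Malay	Individuals who self-report or have been described as South East Asian or one of the sub-populations from this region (e.g. Vietnamese), or who genetically cluster with the KHV reference population.
Sub-Saharan African	African	FALSE		ESN|LWK|GWD|MSL|MKK|YRI	Yoruban|Gambian	Individuals who self-report or have been described as Sub-Saharan African or one of the sub-populations from this region (e.g. Yoruban), or who genetically cluster with reference populations from this region (ESN, LWK, GWD, MSL, MKK, YRI).
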