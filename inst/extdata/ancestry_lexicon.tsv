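descriptor	category	ethnocultural	isolate	admixture_components
Han Chinese	East Asian	FALSE	FALSE	
Taiwanese	East Asian	FALSE	FALSE	
Mongolian	East Asian	FALSE	FALSE	
Japanese American	East Asian	FALSE	FALSE	
Korean American	East Asian	FALSE	FALSE	
Punjabi Sikh	South Asian	TRUE	FALSE	
Sikh	South Asian	TRUE	FALSE	
Asian Indian	South Asian	FALSE	FALSE	
Indian	South Asian	FALSE	FALSE	
Pakistani	South Asian	FALSE	FALSE	
Nepalese	South Asian	FALSE	FALSE	
Sinhalese	South Asian	FALSE	FALSE	
Tamil	South Asian	TRUE	FALSE	
Vietnamese	South East Asian	FALSE	FALSE	
Filipino	South East Asian	FALSE	FALSE	
Indonesian	South East Asian	FALSE	FALSE	
Khmer	South East Asian	FALSE	FALSE	
Uyghur	Central Asian	FALSE	FALSE	
Kazakh	Central Asian	FALSE	FALSE	
Uzbek	Central Asian	FALSE	FALSE	
Tajik	Central Asian	FALSE	FALSE	
Silk Road	Central Asian	FALSE	TRUE	
Old Order Amish	European	FALSE	TRUE	
Amish	European	FALSE	TRUE	
Old Order Mennonite	European	FALSE	TRUE	
Hutterite	European	FALSE	TRUE	
Ashkenazi Jewish	European	TRUE	TRUE	
Sardinian	European	FALSE	TRUE	
Roma	European	TRUE	FALSE	
Icelandic	European	FALSE	FALSE	
Finnish	European	FALSE	FALSE	
Norwegian	European	FALSE	FALSE	
Danish	European	FALSE	FALSE	
British	European	FALSE	FALSE	
Irish	European	FALSE	FALSE	
Scottish	European	FALSE	FALSE	
German	European	FALSE	FALSE	
French	European	FALSE	FALSE	
Italian	European	FALSE	FALSE	
Greek	European	FALSE	FALSE	
Polish	European	FALSE	FALSE	
Estonian	European	FALSE	FALSE	
European American	European	FALSE	FALSE	
non-Hispanic white	European	FALSE	FALSE	
Saudi Arabian	Greater Middle Eastern (Middle Eastern, North African, or Persian)	FALSE	FALSE	
Turkish	Greater Middle Eastern (Middle Eastern, North African, or Persian)	FALSE	FALSE	
Egyptian	Greater Middle Eastern (Middle Eastern, North African, or Persian)	FALSE	FALSE	
Moroccan	Greater Middle Eastern (Middle Eastern, North African, or Persian)	FALSE	FALSE	
Qatari	Greater Middle Eastern (Middle Eastern, North African, or Persian)	FALSE	FALSE	
Bedouin	Greater Middle Eastern (Middle Eastern, North African, or Persian)	TRUE	FALSE	
Druze	Greater Middle Eastern (Middle Eastern, North African, or Persian)	TRUE	TRUE	
Native Hawaiian	Oceanian	FALSE	FALSE	
Maori	Oceanian	FALSE	FALSE	
Papuan	Oceanian	FALSE	FALSE	
Tongan	Oceanian	FALSE	FALSE	
Samoan	Oceanian	FALSE	FALSE	
Yoruba	Sub-Saharan African	FALSE	FALSE	
Luhya	Sub-Saharan African	FALSE	FALSE	
Mandinka	Sub-Saharan African	FALSE	FALSE	
Mende	Sub-Saharan African	FALSE	FALSE	
Esan	Sub-Saharan African	FALSE	FALSE	
Maasai	Sub-Saharan African	FALSE	FALSE	
Kenyan	Sub-Saharan African	FALSE	FALSE	
Nigerian	Sub-Saharan African	FALSE	FALSE	
Ghanaian	Sub-Saharan African	FALSE	FALSE	
Ethiopian	Sub-Saharan African	FALSE	FALSE	
Puerto Rican	Hispanic or Latin American	FALSE	FALSE	
Colombian	Hispanic or Latin American	FALSE	FALSE	
Peruvian	Hispanic or Latin American	FALSE	FALSE	
Chilean	Hispanic or Latin American	FALSE	FALSE	
Costa Rican	Hispanic or Latin American	FALSE	FALSE	
Argentinian	Hispanic or Latin American	FALSE	FALSE	
Mexican American	Hispanic or Latin American	FALSE	FALSE	
Mestizo	Hispanic or Latin American	FALSE	FALSE	European|Native American
Pima	Native American	FALSE	FALSE	
Navajo	Native American	FALSE	FALSE	
Martu	Aboriginal Australian	FALSE	FALSE	
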