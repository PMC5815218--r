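cohort
TwinsUK
UK Biobank
Framingham Heart Study
deCODE
FINRISK
Rotterdam Study
ALSPAC
Women's Health Initiative
Jackson Heart Study
KORA
SardiNIA
Generation Scotland
Estonian Biobank
BioBank Japan
China Kadoorie Biobank
Health and Retirement Study
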