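country,region
AFR_REF_country,AFR_R0
AFR_P1_countryA,AFR_R1
AFR_P1_countryB,AFR_R1
AFR_P2_countryA,AFR_R2
AFR_P2_countryB,AFR_R2
AFR_P3_countryA,AFR_R3
AFR_P3_countryB,AFR_R3
EUR_REF_country,EUR_R0
EUR_P1_countryA,EUR_R1
EUR_P1_countryB,EUR_R1
EUR_P2_countryA,EUR_R2
EUR_P2_countryB,EUR_R2
EUR_P3_countryA,EUR_R3
EUR_P3_countryB,EUR_R3
SAS_REF_country,SAS_R0
SAS_P1_countryA,SAS_R1
SAS_P1_countryB,SAS_R1
SAS_P2_countryA,SAS_R2
SAS_P2_countryB,SAS_R2
SAS_P3_countryA,SAS_R3
SAS_P3_countryB,SAS_R3
EAS_REF_country,EAS_R0
EAS_P1_countryA,EAS_R1
EAS_P1_countryB,EAS_R1
EAS_P2_countryA,EAS_R2
EAS_P2_countryB,EAS_R2
EAS_P3_countryA,EAS_R3
EAS_P3_countryB,EAS_R3
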