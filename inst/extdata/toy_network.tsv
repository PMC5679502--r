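id	equation	lower	upper	reversible	tag	acid
EX_GLC	1 glc_e -> 6 c1	0	1000	FALSE	GLUCOSE_EX	NA
EX_XYL	1 xyl_e -> 5 c1	0	1000	FALSE	XYLOSE_EX	NA
PIE	1 pi_e -> 1 p	0	1000	FALSE	EXTERNAL_P_IN	NA
PI	1 pstor -> 1 p	0	1000	FALSE	STORED_P_IN	NA
PSTORE	1 p -> 1 pstor	0	1000	FALSE	STORAGE	NA
BIOMASS	185.68395637332443 c1 + 0.10008394137018144 p -> 148.54716509865955 co2_e	0	1000	FALSE	BIOMASS	NA
OAH	2 c1 -> 1 oxa_c	0	1000	FALSE	OAH	NA
GOX	1 glc_e -> 1 glcn_u	0	1000	FALSE	GOX	NA
SEC_CIT	6 c1 -> 1 cit_u	0	1000	FALSE	ACID_SECRETION	citric
DIS_CIT	1 cit_u -> 1 cit_e + 2.7986459432505697 hp	0	1000	FALSE	ACID_DISSOCIATION	citric
SEC_OXA	1 oxa_c -> 1 oxa_u	0	1000	FALSE	ACID_SECRETION	oxalic
DIS_OXA	1 oxa_u -> 1 oxa_e + 1.9981583758197057 hp	0	1000	FALSE	ACID_DISSOCIATION	oxalic
SEC_GLCN	6 c1 -> 1 glcn_u	0	0	FALSE	ACID_SECRETION	gluconic
DIS_GLCN	1 glcn_u -> 1 glcn_e + 0.99949906382918641 hp	0	1000	FALSE	ACID_DISSOCIATION	gluconic
SEC_ACE	2 c1 -> 1 ace_u	0	0	FALSE	ACID_SECRETION	acetic
DIS_ACE	1 ace_u -> 1 ace_e + 0.99431768683906485 hp	0	1000	FALSE	ACID_DISSOCIATION	acetic
SEC_MAL	4 c1 -> 1 mal_u	0	0	FALSE	ACID_SECRETION	malic
DIS_MAL	1 mal_u -> 1 mal_e + 1.9876447320128312 hp	0	1000	FALSE	ACID_DISSOCIATION	malic
SEC_SUC	4 c1 -> 1 suc_u	0	0	FALSE	ACID_SECRETION	succinic
DIS_SUC	1 suc_u -> 1 suc_e + 1.9584109717877618 hp	0	1000	FALSE	ACID_DISSOCIATION	succinic
SEC_LAC	3 c1 -> 1 lac_u	0	0	FALSE	ACID_SECRETION	lactic
DIS_LAC	1 lac_u -> 1 lac_e + 0.99927608846747107 hp	0	1000	FALSE	ACID_DISSOCIATION	lactic
HPE	1 hp -> 1 h_e	0	1000	FALSE	PROTON_OUT	NA
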