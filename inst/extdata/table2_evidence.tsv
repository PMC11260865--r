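drug_name	target_symbols	max_level	overall_effect	black_box	withdrawn	high_priority
Amiodarone	KCNH2	Guideline	Existing treatment	Pulmonary Toxicity, Hepatotoxicity, Cardiotoxicity	No	FALSE
Atenolol	ADRB1	Guideline	Existing treatment	Cardiotoxicity	No	FALSE
Bepridil	CACNA1G	Guideline	Existing treatment		No	FALSE
Bisoprolol	ADRB1	Guideline	Existing treatment		No	FALSE
Carvedilol	ADRA1A, ADRB1	Guideline	Existing treatment		No	FALSE
Disopyramide	SCN10A, SCN5A	Guideline	Existing treatment	Cardiotoxicity	No	TRUE
Dofetilide	KCNH2	Guideline	Existing treatment	Cardiotoxicity	No	FALSE
Dronedarone	HCN4, KCNJ2, SCN10A, SCN5A	Guideline	Existing treatment	Mortaility Risk	No	TRUE
Esmolol	ADRB1	Guideline	Existing treatment		No	FALSE
Flecainide	SCN5A	Guideline	Existing treatment	Cardiotoxicity	No	TRUE
Ibutilide	KCNH2	Guideline	Existing treatment	Cardiotoxicity	No	FALSE
Landiolol	ADRB1	Guideline	Existing treatment		No	FALSE
Metoprolol	ADRB1	Guideline	Existing treatment		No	FALSE
Nadolol	ADRB1	Guideline	Existing treatment	Cardiotoxicity	No	FALSE
Nebivolol	ADRB1	Guideline	Existing treatment		No	FALSE
Procainamide	SCN10A, SCN5A	Guideline	Existing treatment	Musculoskeletatl Toxicity, Haematological Toxicity, Cardiotoxicity	No	TRUE
Propafenone	ADRB1, SCN10A, SCN5A	Guideline	Existing treatment	Mortaility Risk	No	TRUE
Propranolol	ADRB1	Guideline	Existing treatment	Cardiotoxicity	No	FALSE
Quinidine	SCN10A, SCN5A	Guideline	Existing treatment	Cardiotoxicity	No	TRUE
Sotalol	ADRB1, KCNH2	Guideline	Existing treatment	Cardiotoxicity	No	TRUE
Vernakalant	KCND3, KCNH2, KCNJ5, SCN5A	Guideline	Existing treatment		No	TRUE
Colchicine	TUBB3	Systematic Review	Beneficial		No	FALSE
Methylprednisolone	NR3C1	Systematic Review	Beneficial		No	TRUE
Acebutolol	ADRB1	Systematic Review	Beneficial		No	FALSE
Dexamethasone	NR3C1	Systematic Review	Beneficial		No	TRUE
Hydrocortisone	NR3C1	Systematic Review	Neutral		No	TRUE
Ivabradine	HCN4	Systematic Review	Harmful		No	TRUE
Liothyronine	THRB	Systematic review	Neutral	Against use in weight loss	No	TRUE
Mavacamtam	MYH6, MYH7, MYL4	Systematic Review	Neutral		No	TRUE
Roflumilast	PDE4B	Systematic Review	Beneficial		No	TRUE
Timolol	ADRB1	Systematic Review	Beneficial		No	FALSE
Prednisolone	NR3C1	RCT	Neutral		No	FALSE
AZD1305	KCNH2, SCN5A	RCT	Beneficial		No	TRUE
AZD7009	KCNH2, SCN5A	RCT	Beneficial		No	TRUE
Beclomethasone Dipropionate	NR3C1	RCT	Beneficial		No	TRUE
Betaxolol	ADRB1	RCT	Neutral (Compared with other drug in same class)		No	FALSE
Bucindolol	ADRA1A, ADRB1	RCT	Beneficial (Compared with other drug in same class)		No	FALSE
Carperitide	NPR3	RCT	Beneficial		No	TRUE
Cilostazol	PDE3A	RCT	Harmful	Contraindicated In Heart Failure	No	FALSE
Conjugated Estrogens	ESR2	RCT	Neutral	Endometrial cancer risk, Cariovascular risk, Dementia risk	No	TRUE
Dobutamine	ADRB1	RCT	Neutral (Compared with other drug in same class)		No	FALSE
Doxazosin	ADRA1A	RCT	Harmful		No	FALSE
Duloxetine	SLC6A4	RCT	Neutral	Psychiatric Toxicity	No	FALSE
Erlosamide	SCN10A, SCN5A	RCT	Neutral		No	TRUE
Isoproterenol	ADRB1	RCT	Neutral (Compared with other drug in same class)		No	FALSE
Levosimendan	PDE3A, TNNI3	RCT	Mixed		No	FALSE
Lidocaine	SCN10A, SCN5A	RCT	Beneficial	For strict dosing under the age of 3 otherwise mortaility risk	No	TRUE
Meprednisone	NR3C1	RCT	Neutral		No	TRUE
Milrinone	PDE3A	RCT	Beneficial		No	FALSE
Nomifensine	SLC6A4	RCT	Neutral		Yes	FALSE
Omecamtiv Mecarbil	MYH6, MYH7, MYL4	RCT	Neutral		No	TRUE
Prednisone	NR3C1	RCT	Neutral		No	TRUE
Ranolazine	SCN5A	RCT	Beneficial		No	TRUE
Tedisamil	KCND3, KCNH2	RCT	Beneficial		No	TRUE
Theophylline	PDE3A, PDE4B	RCT	Neutral		No	TRUE
Tosedostat	AOPEP (C9orf3), ENPEP	RCT	Harmful		No	TRUE
Vinorelbine	TUBB3	RCT	Harmful	Haematological Toxicity, Infectious Disease	No	FALSE
Bortezomib	PSMB7, PSMD3	Observational	Potential Harm		No	TRUE
Abiraterone	SRD5A3	Observational	Potential Harm		No	FALSE
Carfilzomib	PSMB7, PSMD3	Observational	Potential Harm		No	TRUE
Cocaine	SCN10A, SCN5A	Observational	Potential Harm	Misuse	No	TRUE
Docetaxel	TUBB3	Observational	Potential Harm	Gastrointestinal Toxicity, Haematological Toxicity, Respiratory Toxicity, Dermatological Toxicity, Vascular Toxicity, Immune System Toxicity, Hepatotoxicity	No	FALSE
Elotuzumab	SLAMF7	Observational	Potential Harm		No	FALSE
Ixazomib	PSMB7, PSMD3	Observational	Potential Harm		No	TRUE
Levothyroxine	THRB	Observational	Potential Harm	Against use in weight loss	No	TRUE
Metformin	NDUFAF3, NDUFB10	Observational	Mixed		No	TRUE
Methamphetamine	SLC6A4	Observational	Potential Harm		Yes	FALSE
Midostaurin	PRKCA	Observational	Potential Harm		No	TRUE
Raloxifene	ESR2	Observational	Neutral	Respiratory Toxicity, Vascular Toxicity, Neurotoxicity	No	TRUE
Regorafenib	FGFR1, FGFR2, RAF1	Observational	Potential Harm	Hepatotoxicity	No	FALSE
Sorafenib	RAF1	Observational	Potential Harm		No	FALSE
Trastuzumab	ERBB2	Observational	Neutral	Teratogenicity, Cardiotoxicity, Respiratory Toxicity	No	TRUE
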