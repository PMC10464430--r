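icd_prefix,cause_l4,cause_l3,cause_l2,cause_l1,idd_class,target_codes,package_id
I20,ischemic_heart_disease,ischemic_heart_disease,cardiovascular_diseases,NCD,specific,,
I21,ischemic_heart_disease,ischemic_heart_disease,cardiovascular_diseases,NCD,specific,,
I22,ischemic_heart_disease,ischemic_heart_disease,cardiovascular_diseases,NCD,specific,,
I24,ischemic_heart_disease,ischemic_heart_disease,cardiovascular_diseases,NCD,specific,,
I25,ischemic_heart_disease,ischemic_heart_disease,cardiovascular_diseases,NCD,specific,,
I60,hemorrhagic_stroke,cerebrovascular_disease,cardiovascular_diseases,NCD,specific,,
I61,hemorrhagic_stroke,cerebrovascular_disease,cardiovascular_diseases,NCD,specific,,
I62,hemorrhagic_stroke,cerebrovascular_disease,cardiovascular_diseases,NCD,specific,,
I63,ischemic_stroke,cerebrovascular_disease,cardiovascular_diseases,NCD,specific,,
I10,hypertensive_heart_disease,hypertensive_heart_disease,cardiovascular_diseases,NCD,specific,,
I11,hypertensive_heart_disease,hypertensive_heart_disease,cardiovascular_diseases,NCD,specific,,
I48,atrial_fibrillation,atrial_fibrillation,cardiovascular_diseases,NCD,specific,,
I70,other_cardiovascular,other_cardiovascular,cardiovascular_diseases,NCD,specific,,
I71,other_cardiovascular,other_cardiovascular,cardiovascular_diseases,NCD,specific,,
I72,other_cardiovascular,other_cardiovascular,cardiovascular_diseases,NCD,specific,,
C33,lung_cancer,lung_cancer,neoplasms,NCD,specific,,
C34,lung_cancer,lung_cancer,neoplasms,NCD,specific,,
C50,breast_cancer,breast_cancer,neoplasms,NCD,specific,,
C53,cervical_cancer,cervical_cancer,neoplasms,NCD,specific,,
C54,uterine_cancer,uterine_cancer,neoplasms,NCD,specific,,
C61,prostate_cancer,prostate_cancer,neoplasms,NCD,specific,,
C18,colorectal_cancer,colorectal_cancer,neoplasms,NCD,specific,,
C19,colorectal_cancer,colorectal_cancer,neoplasms,NCD,specific,,
C20,colorectal_cancer,colorectal_cancer,neoplasms,NCD,specific,,
C25,pancreatic_cancer,pancreatic_cancer,neoplasms,NCD,specific,,
E10,diabetes_mellitus,diabetes_mellitus,diabetes_kidney_diseases,NCD,specific,,
E11,diabetes_mellitus,diabetes_mellitus,diabetes_kidney_diseases,NCD,specific,,
E14,diabetes_mellitus,diabetes_mellitus,diabetes_kidney_diseases,NCD,specific,,
N18,chronic_kidney_disease,chronic_kidney_disease,diabetes_kidney_diseases,NCD,specific,,
G30,alzheimers_dementias,alzheimers_dementias,neurological_disorders,NCD,specific,,
F01,alzheimers_dementias,alzheimers_dementias,neurological_disorders,NCD,specific,,
G20,parkinsons_disease,parkinsons_disease,neurological_disorders,NCD,specific,,
J43,copd,copd,chronic_respiratory_diseases,NCD,specific,,
J44,copd,copd,chronic_respiratory_diseases,NCD,specific,,
J45,asthma,asthma,chronic_respiratory_diseases,NCD,specific,,
F10,alcohol_use_disorders,alcohol_use_disorders,substance_use_disorders,NCD,specific,,
F11,drug_use_disorders,drug_use_disorders,substance_use_disorders,NCD,specific,,
F12,drug_use_disorders,drug_use_disorders,substance_use_disorders,NCD,specific,,
F13,drug_use_disorders,drug_use_disorders,substance_use_disorders,NCD,specific,,
F14,drug_use_disorders,drug_use_disorders,substance_use_disorders,NCD,specific,,
F15,drug_use_disorders,drug_use_disorders,substance_use_disorders,NCD,specific,,
F16,drug_use_disorders,drug_use_disorders,substance_use_disorders,NCD,specific,,
F19,drug_use_disorders,drug_use_disorders,substance_use_disorders,NCD,specific,,
K70,cirrhosis,cirrhosis,digestive_diseases,NCD,specific,,
K74,cirrhosis,cirrhosis,digestive_diseases,NCD,specific,,
J12,lower_respiratory_infections,lower_respiratory_infections,respiratory_infections,CMNN,specific,,
J13,lower_respiratory_infections,lower_respiratory_infections,respiratory_infections,CMNN,specific,,
J14,lower_respiratory_infections,lower_respiratory_infections,respiratory_infections,CMNN,specific,,
J15,lower_respiratory_infections,lower_respiratory_infections,respiratory_infections,CMNN,specific,,
J16,lower_respiratory_infections,lower_respiratory_infections,respiratory_infections,CMNN,specific,,
J18,lower_respiratory_infections,lower_respiratory_infections,respiratory_infections,CMNN,specific,,
A08,diarrheal_diseases,diarrheal_diseases,enteric_infections,CMNN,specific,,
A09,diarrheal_diseases,diarrheal_diseases,enteric_infections,CMNN,specific,,
A82,rabies,rabies,other_infectious_diseases,CMNN,specific,,
V03,road_injuries,road_injuries,transport_injuries,injuries,specific,,
V09,road_injuries,road_injuries,transport_injuries,injuries,specific,,
V43,road_injuries,road_injuries,transport_injuries,injuries,specific,,
V47,road_injuries,road_injuries,transport_injuries,injuries,specific,,
V89,road_injuries,road_injuries,transport_injuries,injuries,specific,,
W01,falls,falls,unintentional_injuries,injuries,specific,,
W06,falls,falls,unintentional_injuries,injuries,specific,,
W10,falls,falls,unintentional_injuries,injuries,specific,,
W18,falls,falls,unintentional_injuries,injuries,specific,,
W19,falls,falls,unintentional_injuries,injuries,specific,,
X41,accidental_poisoning,accidental_poisoning,unintentional_injuries,injuries,specific,,
X42,accidental_poisoning,accidental_poisoning,unintentional_injuries,injuries,specific,,
X44,accidental_poisoning,accidental_poisoning,unintentional_injuries,injuries,specific,,
X60,self_harm,self_harm,self_harm_violence,injuries,specific,,
X61,self_harm,self_harm,self_harm_violence,injuries,specific,,
X62,self_harm,self_harm,self_harm_violence,injuries,specific,,
X64,self_harm,self_harm,self_harm_violence,injuries,specific,,
X70,self_harm,self_harm,self_harm_violence,injuries,specific,,
X74,self_harm,self_harm,self_harm_violence,injuries,specific,,
X80,self_harm,self_harm,self_harm_violence,injuries,specific,,
X84,self_harm,self_harm,self_harm_violence,injuries,specific,,
C55,,,,,icd_targeted,C53;C54,
C80,,,,,icd_targeted,C33;C34;C50;C53;C54;C61;C18;C19;C20;C25,
J98,,,,,icd_targeted,J43;J44;J45,
K72,,,,,icd_targeted,K70;K74,
J189,,,,,icd_targeted,J12;J13;J14;J15;J16,
I64,,,,,icd_targeted,I60;I61;I63,
F03,,,,,icd_targeted,G30;F01,
Y10,,,,,icd_targeted,X41;X42;X44;X60;X61;X62;X64,
Y11,,,,,icd_targeted,X41;X42;X44;X60;X61;X62;X64,
Y12,,,,,icd_targeted,X41;X42;X44;X60;X61;X62;X64,
I50,,,,,packaged,,heart_failure
N19,,,,,packaged,,acute_kidney_failure
N170,,,,,packaged,,acute_kidney_failure
N179,,,,,packaged,,acute_kidney_failure
I46,,,,,unassigned,,
R54,,,,,unassigned,,
R96,,,,,unassigned,,
R98,,,,,unassigned,,
R99,,,,,unassigned,,
Y34,,,,,icd_targeted,V03;V09;V43;V47;V89;W01;W06;W10;W18;W19;X41;X42;X44;X60;X61;X62;X64;X70;X74;X80;X84,
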