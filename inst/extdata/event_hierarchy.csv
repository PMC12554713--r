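pt,hlt,hlgt,soc
OSTEOPENIA,METABOLIC BONE DISORDERS,BONE DISORDERS,MUSCULOSKELETAL AND CONNECTIVE TISSUE DISORDERS
OSTEOPOROSIS,METABOLIC BONE DISORDERS,BONE DISORDERS,MUSCULOSKELETAL AND CONNECTIVE TISSUE DISORDERS
ARTHRALGIA,JOINT SIGNS AND SYMPTOMS,JOINT DISORDERS,MUSCULOSKELETAL AND CONNECTIVE TISSUE DISORDERS
MYALGIA,MUSCLE PAINS,MUSCLE DISORDERS,MUSCULOSKELETAL AND CONNECTIVE TISSUE DISORDERS
SEIZURE,SEIZURES NEC,SEIZURES,NERVOUS SYSTEM DISORDERS
DIZZINESS,NEUROLOGICAL SIGNS AND SYMPTOMS NEC,NEUROLOGICAL DISORDERS NEC,NERVOUS SYSTEM DISORDERS
SOMNOLENCE,DISTURBANCES IN CONSCIOUSNESS NEC,NEUROLOGICAL DISORDERS NEC,NERVOUS SYSTEM DISORDERS
HEADACHE,HEADACHES NEC,HEADACHES,NERVOUS SYSTEM DISORDERS
TREMOR,TREMOR,MOVEMENT DISORDERS,NERVOUS SYSTEM DISORDERS
MEMORY IMPAIRMENT,MEMORY LOSS,MENTAL IMPAIRMENT DISORDERS,NERVOUS SYSTEM DISORDERS
FATIGUE,ASTHENIC CONDITIONS,GENERAL SYSTEM DISORDERS NEC,GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS
DRUG INEFFECTIVE,THERAPEUTIC RESPONSES,THERAPEUTIC AND NONTHERAPEUTIC RESPONSES,GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS
PYREXIA,FEBRILE DISORDERS,BODY TEMPERATURE CONDITIONS,GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS
MALAISE,ASTHENIC CONDITIONS,GENERAL SYSTEM DISORDERS NEC,GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS
GAIT DISTURBANCE,MOBILITY DECREASED,GENERAL SYSTEM DISORDERS NEC,GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS
NAUSEA,NAUSEA AND VOMITING SYMPTOMS,GASTROINTESTINAL MOTILITY AND DEFAECATION CONDITIONS,GASTROINTESTINAL DISORDERS
VOMITING,NAUSEA AND VOMITING SYMPTOMS,GASTROINTESTINAL MOTILITY AND DEFAECATION CONDITIONS,GASTROINTESTINAL DISORDERS
DIARRHOEA,DIARRHOEA,GASTROINTESTINAL MOTILITY AND DEFAECATION CONDITIONS,GASTROINTESTINAL DISORDERS
RASH,RASHES ERUPTIONS AND EXANTHEMS NEC,EPIDERMAL AND DERMAL CONDITIONS,SKIN AND SUBCUTANEOUS TISSUE DISORDERS
PRURITUS,PRURITUS NEC,EPIDERMAL AND DERMAL CONDITIONS,SKIN AND SUBCUTANEOUS TISSUE DISORDERS
ALOPECIA,ALOPECIAS,HAIR AND HAIRSTYLE CONDITIONS,SKIN AND SUBCUTANEOUS TISSUE DISORDERS
DEPRESSION,DEPRESSIVE DISORDERS,MOOD DISORDERS AND DISTURBANCES,PSYCHIATRIC DISORDERS
ANXIETY,ANXIETY SYMPTOMS,ANXIETY DISORDERS AND SYMPTOMS,PSYCHIATRIC DISORDERS
CONFUSIONAL STATE,CONFUSION AND DISORIENTATION,DELIRIA,PSYCHIATRIC DISORDERS
SUICIDAL IDEATION,SUICIDAL AND SELF-INJURIOUS BEHAVIOUR,SUICIDAL BEHAVIOURS,PSYCHIATRIC DISORDERS
ANAEMIA,ANAEMIAS NEC,ANAEMIAS NONHAEMOLYTIC AND MARROW DEPRESSION,BLOOD AND LYMPHATIC SYSTEM DISORDERS
THROMBOCYTOPENIA,THROMBOCYTOPENIAS,PLATELET DISORDERS,BLOOD AND LYMPHATIC SYSTEM DISORDERS
PALPITATIONS,CARDIAC SIGNS AND SYMPTOMS NEC,CARDIAC DISORDER SIGNS AND SYMPTOMS,CARDIAC DISORDERS
BRADYCARDIA,RATE AND RHYTHM DISORDERS NEC,CARDIAC ARRHYTHMIAS,CARDIAC DISORDERS
VERTIGO,INNER EAR SIGNS AND SYMPTOMS,INNER EAR AND VIIITH CRANIAL NERVE DISORDERS,EAR AND LABYRINTH DISORDERS
TINNITUS,INNER EAR SIGNS AND SYMPTOMS,INNER EAR AND VIIITH CRANIAL NERVE DISORDERS,EAR AND LABYRINTH DISORDERS
HYPOTHYROIDISM,THYROID HYPOFUNCTION DISORDERS,THYROID GLAND DISORDERS,ENDOCRINE DISORDERS
HYPERPARATHYROIDISM,PARATHYROID GLAND DISORDERS,PARATHYROID GLAND DISORDERS,ENDOCRINE DISORDERS
VISION BLURRED,VISUAL DISORDERS NEC,VISION DISORDERS,EYE DISORDERS
DIPLOPIA,OCULAR MOTILITY DISORDERS,OCULAR NEUROMUSCULAR DISORDERS,EYE DISORDERS
HEPATOTOXICITY,HEPATOCELLULAR DAMAGE NEC,HEPATIC AND HEPATOBILIARY DISORDERS,HEPATOBILIARY DISORDERS
HYPERAMMONAEMIA,HEPATIC ENZYME AND FUNCTION ABNORMALITIES,HEPATIC AND HEPATOBILIARY DISORDERS,HEPATOBILIARY DISORDERS
DRUG HYPERSENSITIVITY,ALLERGIC CONDITIONS NEC,ALLERGIC CONDITIONS,IMMUNE SYSTEM DISORDERS
ANAPHYLACTIC REACTION,ANAPHYLACTIC RESPONSES,ALLERGIC CONDITIONS,IMMUNE SYSTEM DISORDERS
PNEUMONIA,LOWER RESPIRATORY TRACT INFECTIONS,INFECTIONS - PATHOGEN UNSPECIFIED,INFECTIONS AND INFESTATIONS
URINARY TRACT INFECTION,URINARY TRACT INFECTIONS,INFECTIONS - PATHOGEN UNSPECIFIED,INFECTIONS AND INFESTATIONS
FALL,NON-SITE SPECIFIC INJURIES NEC,INJURIES NEC,"INJURY, POISONING AND PROCEDURAL COMPLICATIONS"
OVERDOSE,OVERDOSES,MEDICATION ERRORS AND OTHER PRODUCT USE ERRORS AND ISSUES,"INJURY, POISONING AND PROCEDURAL COMPLICATIONS"
TOXICITY TO VARIOUS AGENTS,POISONING AND TOXICITY,EXPOSURES CHEMICAL INJURIES AND POISONING,"INJURY, POISONING AND PROCEDURAL COMPLICATIONS"
BLOOD VITAMIN D DECREASED,VITAMIN ANALYSES,METABOLIC INVESTIGATIONS,INVESTIGATIONS
BONE DENSITY DECREASED,MUSCULOSKELETAL AND SOFT TISSUE IMAGING PROCEDURES,MUSCULOSKELETAL AND SOFT TISSUE INVESTIGATIONS,INVESTIGATIONS
WEIGHT DECREASED,PHYSICAL EXAMINATION PROCEDURES,PHYSICAL EXAMINATION TOPICS,INVESTIGATIONS
BLOOD CALCIUM DECREASED,CALCIUM ANALYSES,METABOLIC INVESTIGATIONS,INVESTIGATIONS
DECREASED APPETITE,APPETITE DISORDERS,APPETITE AND GENERAL NUTRITIONAL DISORDERS,METABOLISM AND NUTRITION DISORDERS
HYPONATRAEMIA,SODIUM IMBALANCE,ELECTROLYTE AND FLUID BALANCE CONDITIONS,METABOLISM AND NUTRITION DISORDERS
VITAMIN D DEFICIENCY,VITAMIN DEFICIENCIES,VITAMIN RELATED DISORDERS,METABOLISM AND NUTRITION DISORDERS
RENAL IMPAIRMENT,RENAL FAILURE AND IMPAIRMENT,RENAL DISORDERS,RENAL AND URINARY DISORDERS
NEPHROLITHIASIS,URINARY TRACT LITHIASIS,URINARY TRACT SIGNS AND SYMPTOMS,RENAL AND URINARY DISORDERS
DYSPNOEA,BREATHING ABNORMALITIES,RESPIRATORY DISORDERS NEC,"RESPIRATORY, THORACIC AND MEDIASTINAL DISORDERS"
COUGH,COUGHING AND ASSOCIATED SYMPTOMS,RESPIRATORY DISORDERS NEC,"RESPIRATORY, THORACIC AND MEDIASTINAL DISORDERS"
HYPOTENSION,VASCULAR HYPOTENSIVE DISORDERS,DECREASED AND NONSPECIFIC BLOOD PRESSURE DISORDERS AND SHOCK,VASCULAR DISORDERS
HYPERTENSION,VASCULAR HYPERTENSIVE DISORDERS NEC,BLOOD PRESSURE INCREASED,VASCULAR DISORDERS
FOETAL ANTICONVULSANT SYNDROME,FOETAL COMPLICATIONS,FOETAL COMPLICATIONS OF PREGNANCY,"PREGNANCY, PUERPERIUM AND PERINATAL CONDITIONS"
ABORTION SPONTANEOUS,ABORTIONS SPONTANEOUS,ABORTIONS AND STILLBIRTH,"PREGNANCY, PUERPERIUM AND PERINATAL CONDITIONS"
CONGENITAL ANOMALY,CONGENITAL DISORDERS NEC,CONGENITAL DISORDERS,"CONGENITAL, FAMILIAL AND GENETIC DISORDERS"
SPINA BIFIDA,NEURAL TUBE DEFECTS,CONGENITAL NERVOUS SYSTEM DISORDERS,"CONGENITAL, FAMILIAL AND GENETIC DISORDERS"
ERECTILE DYSFUNCTION,ERECTION AND EJACULATION DISORDERS,SEXUAL FUNCTION AND FERTILITY DISORDERS,REPRODUCTIVE SYSTEM AND BREAST DISORDERS
GYNAECOMASTIA,BREAST ENLARGEMENT AND GYNAECOMASTIA,BREAST DISORDERS NEC,REPRODUCTIVE SYSTEM AND BREAST DISORDERS
LYMPHADENOPATHY,LYMPHATIC SYSTEM DISORDERS NEC,LYMPHATIC SYSTEM DISORDERS,BLOOD AND LYMPHATIC SYSTEM DISORDERS
BASAL CELL CARCINOMA,SKIN NEOPLASMS MALIGNANT,SKIN NEOPLASMS MALIGNANT AND UNSPECIFIED,"NEOPLASMS BENIGN, MALIGNANT AND UNSPECIFIED (INCL CYSTS AND POLYPS)"
LYMPHOMA,LYMPHOMAS NEC,LYMPHOMAS NON-HODGKIN'S,"NEOPLASMS BENIGN, MALIGNANT AND UNSPECIFIED (INCL CYSTS AND POLYPS)"
GINGIVAL HYPERPLASIA,GINGIVAL DISORDERS,DENTAL AND GINGIVAL CONDITIONS,GASTROINTESTINAL DISORDERS
DEATH,DEATH AND SUDDEN DEATH,FATAL OUTCOMES,GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS
HEARING IMPAIRED,HEARING LOSSES,HEARING DISORDERS,EAR AND LABYRINTH DISORDERS
EOSINOPHILIA,EOSINOPHILIC DISORDERS,WHITE BLOOD CELL DISORDERS,BLOOD AND LYMPHATIC SYSTEM DISORDERS
DEVICE MALFUNCTION,DEVICE MALFUNCTION EVENTS NEC,DEVICE ISSUES,PRODUCT ISSUES
PRODUCT QUALITY ISSUE,PRODUCT QUALITY ISSUES NEC,PRODUCT QUALITY ISSUES,PRODUCT ISSUES
ECONOMIC PROBLEM,ECONOMIC ISSUES,SOCIAL ENVIRONMENT ISSUES,SOCIAL CIRCUMSTANCES
SURGERY,THERAPEUTIC PROCEDURES NEC,THERAPEUTIC PROCEDURES AND SUPPORTIVE CARE NEC,SURGICAL AND MEDICAL PROCEDURES
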