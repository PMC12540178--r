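pt,n,ror025,deaths,designation,evidence,published_score,published_category
Nausea,65,1.80,0,none,++,4,weak
Fatigue,65,1.83,0,none,++,4,weak
Diarrhoea,61,2.08,0,none,++,5,moderate
Headache,39,1.25,1,none,++,3,weak
Rash,29,1.22,0,none,++,3,weak
Abdominal discomfort,27,2.99,0,none,++,4,weak
Hypertension,24,2.08,0,none,++,4,weak
Alopecia,23,2.12,0,none,-,2,weak
Pneumonia,23,1.23,4,IME,++,4,weak
Infection,22,2.8,3,none,++,4,weak
Upper abdominal pain,22,1.96,0,none,++,3,weak
Cough,21,1.36,0,none,+,2,weak
Swelling face,18,4.81,0,none,++,4,weak
Blood pressure increased,18,2.02,0,none,++,4,weak
Hepatic enzyme increased,18,4.66,0,none,++,4,weak
Peripheral swelling,16,1.78,0,none,++,3,weak
Liver disorder,10,3.35,1,none,++,4,weak
Hepatic function abnormal,10,4.04,0,none,++,4,weak
Swelling,9,1.15,0,none,++,2,weak
Blood creatinine increased,8,1.65,0,none,++,2,weak
Liver function test increased,8,5.37,0,none,++,4,weak
Drug-induced liver injury,8,3.83,0,DME,++,5,moderate
Aspartate aminotransferase increased,7,1.70,0,none,++,2,weak
Alanine aminotransferase increased,7,1.47,0,none,++,2,weak
Pollakiuria,6,1.78,0,none,++,2,weak
Increased appetite,5,3.27,0,none,-,1,weak
Blood alkaline phosphatase increased,5,2.22,0,none,++,3,weak
Blood pressure abnormal,4,2.12,0,none,++,3,weak
Localised infection,4,1.70,0,none,++,2,weak
Muscle atrophy,3,2.17,0,none,-,1,weak
Oesophageal disorder,3,6.75,0,none,-,2,weak
Pharyngeal swelling,3,2.97,0,none,++,3,weak
Hyperaesthesia teeth,3,8.85,0,none,-,2,weak
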