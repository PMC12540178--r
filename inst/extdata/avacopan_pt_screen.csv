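pt,n,ror,ci_low,ci_high,ic,ic025
Nausea,65,2.31,1.80,2.96,1.18,0.8
Fatigue,65,2.34,1.83,3.0,1.2,0.81
Diarrhoea,61,2.68,2.08,3.46,1.4,0.99
Headache,39,1.72,1.25,2.36,0.77,0.28
Rash,29,1.76,1.22,2.55,0.81,0.24
Abdominal discomfort,27,4.36,2.99,6.38,2.11,1.4
Hypertension,24,3.12,2.08,4.66,1.63,0.93
Alopecia,23,3.2,2.12,4.83,1.67,0.95
Pneumonia,23,1.85,1.23,2.79,0.88,0.24
Infection,22,4.27,2.8,6.5,2.08,1.29
Upper abdominal pain,22,2.99,1.96,4.54,1.57,0.84
Cough,21,2.08,1.36,3.2,1.05,0.37
Swelling face,18,7.64,4.81,12.16,2.92,1.83
Blood pressure increased,18,3.22,2.02,5.11,1.68,0.85
Hepatic enzyme increased,18,7.41,4.66,11.78,2.88,1.80
Peripheral swelling,16,2.92,1.78,4.77,1.54,0.68
Liver disorder,10,6.23,3.35,11.6,2.63,1.20
Hepatic function abnormal,10,7.52,4.04,13.99,2.9,1.36
Swelling,9,2.22,1.15,4.28,1.15,0.07
Blood creatinine increased,8,3.3,1.65,6.62,1.72,0.43
Liver function test increased,8,10.75,5.37,21.52,3.42,1.40
Drug-induced liver injury,8,7.66,3.83,15.34,2.93,1.17
Aspartate aminotransferase increased,7,3.57,1.70,7.49,1.83,0.41
Alanine aminotransferase increased,7,3.09,1.47,6.48,1.62,0.27
Pollakiuria,6,3.97,1.78,8.85,1.99,0.38
Increased appetite,5,7.86,3.27,18.9,2.97,0.69
Blood alkaline phosphatase increased,5,5.35,2.22,12.86,2.42,0.45
Blood pressure abnormal,4,5.66,2.12,15.1,2.5,0.26
Localised infection,4,4.52,1.70,12.07,2.18,0.11
Muscle atrophy,3,6.72,2.17,20.86,2.75,0.02
Oesophageal disorder,3,20.96,6.75,65.07,4.39,0.36
Pharyngeal swelling,3,9.21,2.97,28.59,3.2,0.15
Hyperaesthesia teeth,3,27.47,8.85,85.28,4.78,0.41
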