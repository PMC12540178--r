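soc,n,ror,ci_low,ci_high,ic,ic025
General disorders and administration site conditions,421,1.08,0.97,1.2,0.09,-0.06
Gastrointestinal disorders,296,1.62,1.43,1.83,0.62,0.44
Surgical and medical procedures,204,7.16,6.2,8.27,2.72,2.47
Infections and infestations,186,1.61,1.38,1.87,0.64,0.41
"Injury, poisoning and procedural complications",185,0.76,0.65,0.88,-0.36,-0.58
Nervous system disorders,152,0.78,0.66,0.92,-0.33,-0.57
Investigations,140,1.01,0.85,1.2,0.01,-0.24
"Respiratory, thoracic and mediastinal disorders",119,1.12,0.93,1.35,0.16,-0.11
Skin and subcutaneous tissue disorders,106,0.86,0.7,1.04,-0.21,-0.5
Musculoskeletal and connective tissue disorders,93,0.78,0.64,0.96,-0.34,-0.64
Vascular disorders,63,1.32,1.03,1.69,0.39,0.02
Renal and urinary disorders,56,1.32,1.01,1.72,0.39,-0.01
Psychiatric disorders,46,0.35,0.26,0.47,-1.46,-1.86
Hepatobiliary disorders,43,2.08,1.54,2.81,1.04,0.57
Eye disorders,32,0.7,0.5,1.0,-0.5,-0.99
Metabolism and nutrition disorders,31,0.63,0.44,0.9,-0.66,-1.16
Cardiac disorders,26,0.43,0.3,0.64,-1.18,-1.71
Immune system disorders,22,0.87,0.57,1.33,-0.19,-0.79
Ear and labyrinth disorders,17,1.74,1.08,2.81,0.8,0.05
Blood and lymphatic system disorders,11,0.28,0.16,0.51,-1.8,-2.55
Product issues,7,0.18,0.09,0.39,-2.42,-3.29
Social circumstances,4,0.37,0.14,1.0,-1.41,-2.51
"Neoplasms benign, malignant and unspecified (incl cysts and polyps)",3,0.05,0.02,0.15,-4.29,-5.34
Endocrine disorders,2,0.34,0.09,1.37,-1.54,-2.85
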