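section,category,n,published_pct
total,reports,1128,100
sex,female,530,47.0
sex,male,320,28.4
sex,missing,278,24.6
age,<18,13,1.2
age,18-45,151,13.4
age,45-65,329,29.2
age,>=65,310,27.5
age,unknown,325,28.8
outcome,hospitalization,220,19.5
outcome,death,78,6.9
outcome,life-threatening,5,0.4
outcome,disability,2,0.2
outcome,other,823,73.0
country,US,1007,89.3
country,JP,57,5.1
country,CA,31,2.7
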