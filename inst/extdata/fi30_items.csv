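item_id,name,source,levels
1,Self-rated health status,self-report,Good=0|Average=0.5|Poor Health=1
2,Difficulty with hearing,self-report,No=0|Yes=1
3,Cataracts,self-report,No=0|Yes=1
4,Difficulty with vision,self-report,No=0|Yes=1
5,Anemia,self-report,No=0|Yes=1
6,Angina,self-report,No=0|Yes=1
7,Asthma,self-report,No=0|Yes=1
8,Balance (assistance standing 10 s with one foot behind the other),performance,No=0|Yes=1
9,Bathing assistance,self-report,No=0|Yes=1
10,BMI,biomarker,Normal=0|Moderate=0.5|Severe=1
11,Bronchitis,self-report,No=0|Yes=1
12,Stand-ups from chair without using arms,performance,No=0|Yes=1
13,Arthritis,self-report,No=0|Yes=1
14,Toilet assistance,self-report,No=0|Yes=1
15,Loneliness,self-report,No=0|Yes=1
16,Help to carry more than 5 kg,self-report,No=0|Yes=1
17,Random blood sugar (RBS),biomarker,Normal=0|Elevated=0.5|High=1
18,Dressing assistance,self-report,No=0|Yes=1
19,Walking stick use,self-report,No=0|Yes=1
20,Geriatric Depression Scale (GDS-15),self-report,Normal depression=0|Moderate depression=0.5|Severe depression=1
21,Heart attack,self-report,No=0|Yes=1
22,High blood pressure (HBP),biomarker,Normal=0|Mild=0.33|Moderate=0.66|Severe=1
23,Heart murmur,self-report,No=0|Yes=1
24,Heart problem,self-report,No=0|Yes=1
25,Kidney diseases,self-report,No=0|Yes=1
26,Liver diseases,self-report,No=0|Yes=1
27,Osteoporosis,self-report,No=0|Yes=1
28,Seizure,self-report,No=0|Yes=1
29,Stroke,self-report,No=0|Yes=1
30,Urinary infection,self-report,No=0|Yes=1
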