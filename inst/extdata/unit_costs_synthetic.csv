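item,label,sek_per_unit,funding,recall
1,General practitioner,2100,public,1mo
2,Health care professional in home care,1300,public,1mo
3,"Mental health care, private",1150,private,1mo
4,"Mental health care, public",2600,public,1mo
5,Physician in occupational health care,1900,private,1mo
6,Specialist physician,4200,public,3mo
7,Paramedical professional,950,public,3mo
8,Social worker or counselor,1250,public,3mo
9,Clinic for alcohol or drug use,1700,public,3mo
10,Alternative medicine practitioner,750,private,3mo
11,Self-help group,300,private,3mo
12,Psychiatric day care program,3900,public,3mo
13,Inpatient care days,9800,public,3mo
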