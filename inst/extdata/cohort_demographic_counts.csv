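label,n_total,n_term,n_preterm
Hispanic or Latina,24,22,2
White,40,39,1
Black or African American,25,18,7
Asian,4,4,0
Other,23,21,2
No history of conditions,68,63,5
History of conditions,24,19,5
HIV,2,1,1
Herpes,6,5,1
Gonorrhea,3,1,2
Chlamydia,10,7,3
Bacterial vaginosis (BV),13,10,3
Syphilis,1,1,0
Trichomoniasis,9,8,1
Previous pregnancy,71,68,3
Previous PTB,7,5,2
Previous miscarriage,26,23,3
Previous BV,18,16,2
Previous short cervix,1,1,0
Previous low birth weight,4,4,0
Previously homeless,26,22,4
Experienced intimate partner violence,35,30,5
BV Symptoms,16,15,1
BV Treatment,9,9,0
High risk,48,43,5
Addiction counseling,41,38,3
Smoking,40,38,2
Male baby,47,40,7
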