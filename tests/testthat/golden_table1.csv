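"row","ASCT/NA","ASCT/CCNA","ASCT/CA","ASCT/SA","noASCT/NA","noASCT/CCNA","noASCT/CA","noASCT/SA"
"N","1","0","0","0","1","0","1","0"
"Male","1 (100.0)","0 (0.0)","0 (0.0)","0 (0.0)","0 (0.0)","0 (0.0)","1 (100.0)","0 (0.0)"
"Female","0 (0.0)","0 (0.0)","0 (0.0)","0 (0.0)","1 (100.0)","0 (0.0)","0 (0.0)","0 (0.0)"
"Age mean (SD)","50.0 (NA)","","","","62.0 (NA)","","69.0 (NA)",""
"18-29","0 (0.0)","","","","0 (0.0)","","0 (0.0)",""
"30-39","0 (0.0)","","","","0 (0.0)","","0 (0.0)",""
"40-49","0 (0.0)","","","","0 (0.0)","","0 (0.0)",""
"50-59","1 (100.0)","","","","0 (0.0)","","0 (0.0)",""
"60-69","0 (0.0)","","","","1 (100.0)","","1 (100.0)",""
"70-79","0 (0.0)","","","","0 (0.0)","","0 (0.0)",""
">=80","0 (0.0)","","","","0 (0.0)","","0 (0.0)",""
"Follow-up mean (SD)","4.31 (NA)","","","","0.94 (NA)","","2.55 (NA)",""
"Follow-up median (range)","4.31 (4.31-4.31)","","","","0.94 (0.94-0.94)","","2.55 (2.55-2.55)",""
"Follow-up Q1, Q3","4.31, 4.31","","","","0.94, 0.94","","2.55, 2.55",""
"Renal impairment","0 (0.0)","","","","0 (0.0)","","0 (0.0)",""
"Anemia","0 (0.0)","","","","0 (0.0)","","0 (0.0)",""
"Bone fracture","0 (0.0)","","","","0 (0.0)","","0 (0.0)",""
"Pneumonia","0 (0.0)","","","","0 (0.0)","","1 (100.0)",""
"Mean CCI (SD)","0.0 (NA)","","","","0.0 (NA)","","0.0 (NA)",""
"CCI = 0","1 (100.0)","","","","1 (100.0)","","1 (100.0)",""
"CCI = 1","0 (0.0)","","","","0 (0.0)","","0 (0.0)",""
"CCI = 2","0 (0.0)","","","","0 (0.0)","","0 (0.0)",""
"CCI >= 3","0 (0.0)","","","","0 (0.0)","","0 (0.0)",""
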