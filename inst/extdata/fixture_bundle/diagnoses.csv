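"patient_id","claim_date","icd9","position","setting"
"F001","2013-02-01","203.00","primary","outpatient"
"F001","2013-03-01","203.00","secondary","outpatient"
"F002","2010-01-10","486","primary","inpatient"
"F002","2010-06-15","203.0","primary","outpatient"
"F002","2010-08-01","203","secondary","outpatient"
"F003","2013-09-10","203.01","primary","outpatient"
"F003","2013-10-01","203.00","primary","outpatient"
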