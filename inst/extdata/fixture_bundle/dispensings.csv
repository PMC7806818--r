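"patient_id","dispense_date","drug","days_supply","setting"
"F001","2013-02-05","bortezomib",28,"outpatient"
"F001","2013-02-05","thalidomide",28,"outpatient"
"F001","2013-03-05","bortezomib",28,"outpatient"
"F001","2013-03-05","thalidomide",28,"outpatient"
"F002","2010-06-20","melphalan",30,"outpatient"
"F002","2010-07-20","melphalan",30,"outpatient"
"F002","2010-11-01","lenalidomide",28,"outpatient"
"F002","2010-11-29","lenalidomide",28,"outpatient"
"F003","2013-09-15","bortezomib",28,"outpatient"
"F003","2013-09-15","thalidomide",28,"outpatient"
"F003","2013-10-13","bortezomib",28,"outpatient"
"F003","2013-10-13","thalidomide",28,"outpatient"
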