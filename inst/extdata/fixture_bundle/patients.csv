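"patient_id","birth_date","sex","enroll_start","enroll_end"
"F001","1950-03-10","female","2005-01-01",""
"F002","1940-07-22","male","2006-05-01","2012-12-31"
"F003","1962-11-05","male","2011-01-01",""
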