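"condition","icd9_prefixes","weight","supersedes"
"myocardial_infarction","410|412","1",""
"congestive_heart_failure","428","1",""
"peripheral_vascular","441|443.9|785.4|V43.4","1",""
"cerebrovascular","430|431|432|433|434|435|436|437|438","1",""
"dementia","290","1",""
"chronic_pulmonary","490|491|492|493|494|495|496|500|501|502|503|504|505|506.4","1",""
"rheumatologic","710.0|710.1|710.4|714.0|714.1|714.2|714.81|725","1",""
"peptic_ulcer","531|532|533|534","1",""
"mild_liver","571.2|571.4|571.5|571.6","1",""
"diabetes","250.0|250.1|250.2|250.3|250.7","1",""
"diabetes_complicated","250.4|250.5|250.6","2","diabetes"
"hemiplegia_paraplegia","342|344.1","2",""
"renal","582|583.0|583.1|583.2|583.3|583.4|583.5|583.6|583.7|585|586|588","2",""
"malignancy","140|141|142|143|144|145|146|147|148|149|150|151|152|153|154|155|156|157|158|159|160|161|162|163|164|165|166|167|168|169|170|171|172|174|175|176|177|178|179|180|181|182|183|184|185|186|187|188|189|190|191|192|193|194|195|200|201|202|203|204|205|206|207|208","2",""
"moderate_severe_liver","572.2|572.3|572.4|572.5|572.6|572.7|572.8|456.0|456.1|456.2","3","mild_liver"
"metastatic_solid_tumor","196|197|198|199.0|199.1","6","malignancy"
"aids","042|043|044","6",""
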