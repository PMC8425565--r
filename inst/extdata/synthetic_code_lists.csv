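outcome,kind,code,icd10
diabetes,disease,2500014,E10
diabetes,disease,8844022,E10
diabetes,disease,2500027,E10
diabetes,disease,2500013,E11
diabetes,disease,2500029,E14
diabetes,drug,3961007,
diabetes,drug,3969010,
diabetes,drug,2492402,
diabetes,practice,160022410,
diabetes,practice,160022510,
dyslipidemia,disease,2720005,E78
dyslipidemia,disease,2720012,E78
dyslipidemia,disease,2729003,E78
dyslipidemia,drug,2189010,
dyslipidemia,drug,2183005,
dyslipidemia,practice,160022710,
dyslipidemia,practice,160022810,
dyslipidemia,practice,160022910,
hyperthyroidism,disease,2420013,E05
hyperthyroidism,disease,2420005,E05
hyperthyroidism,drug,2432001,
hyperthyroidism,drug,2432400,
hyperthyroidism,drug,2432002,
hyperthyroidism,practice,160023110,
hyperthyroidism,practice,160023210,
acute_renal_failure,disease,5847001,N17
acute_renal_failure,disease,5847013,N17
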