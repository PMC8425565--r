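outcome,def_id,source,stratum,A,subjects,B,C,ppv_printed
diabetes,D1,ssmix,,22086,,4646,17440,21.0% (20.5-21.6)
diabetes,D1,claims,,10647,,1902,8745,17.9% (17.1-18.6)
diabetes,D2,ssmix,,11947,,4538,7409,38.0% (37.1-38.9)
diabetes,D2,claims,,6854,,2043,4811,29.8% (28.7-30.9)
diabetes,D3_1,ssmix,,8092,,3671,4421,45.4% (44.3-46.5)
diabetes,D3_1,claims,,4341,,1696,2645,39.1% (37.6-40.5)
diabetes,D3_2,ssmix,,5212,,2329,2883,44.7% (43.3-46.0)
diabetes,D3_2,claims,,2909,,1149,1760,39.5% (37.7-41.3)
diabetes,D4,claims,,9740,,1831,7909,18.8% (18.0-19.6)
diabetes,D5,claims,,6202,,1968,4234,31.7% (30.6-32.9)
diabetes,D6_1,claims,,4215,,1680,2535,39.9% (38.4-41.3)
diabetes,D6_2,claims,,2785,,1133,1652,40.7% (38.9-42.5)
dyslipidemia,D1,ssmix,,17721,,9588,8133,54.1% (53.4-54.8)
dyslipidemia,D1,claims,,8867,,5276,3591,59.5% (58.5-60.5)
dyslipidemia,D2,ssmix,,14185,,8762,5423,61.8% (61.0-62.6)
dyslipidemia,D2,claims,,7596,,4795,2801,63.1% (62.0-64.2)
dyslipidemia,D3_1,ssmix,,10586,,6752,3834,63.8% (62.9-64.7)
dyslipidemia,D3_1,claims,,6218,,3988,2230,64.1% (62.9-65.3)
dyslipidemia,D3_2,ssmix,,8938,,5581,3357,62.4% (61.4-63.4)
dyslipidemia,D3_2,claims,,5511,,3450,2061,62.6% (61.3-63.9)
dyslipidemia,D4,claims,,6756,,4635,2121,68.6% (67.5-69.7)
dyslipidemia,D5,claims,,5686,,4166,1520,73.3% (72.1-74.4)
dyslipidemia,D6_1,claims,,5025,,3628,1397,72.2% (71.0-73.4)
dyslipidemia,D6_2,claims,,4323,,3091,1232,71.5% (70.2-72.8)
hyperthyroidism,D1,ssmix,,1893,,351,1542,18.5% (16.8-20.3)
hyperthyroidism,D1,claims,,770,,209,561,27.1% (24.0-30.3)
hyperthyroidism,D2,ssmix,,722,,442,280,61.2% (57.7-64.8)
hyperthyroidism,D2,claims,,374,,245,129,65.5% (60.7-70.3)
hyperthyroidism,D3_1,ssmix,,603,,402,201,66.7% (62.9-70.4)
hyperthyroidism,D3_1,claims,,333,,224,109,67.3% (62.2-72.3)
hyperthyroidism,D3_2,ssmix,,447,,313,134,70.0% (65.8-74.3)
hyperthyroidism,D3_2,claims,,242,,168,74,69.4% (63.6-75.2)
hyperthyroidism,D4,claims,,653,,197,456,30.2% (26.6-33.7)
hyperthyroidism,D5,claims,,330,,236,94,71.5% (66.6-76.4)
hyperthyroidism,D6_1,claims,,318,,221,97,69.5% (64.4-74.6)
hyperthyroidism,D6_2,claims,,228,,165,63,72.4% (66.6-78.2)
acute_renal_failure,M2_D1,ssmix,all,1447,432,232,200,53.7% (49.0-58.4)
acute_renal_failure,M2_D1,ssmix,<=1.2,541,162,145,17,89.5% (84.8-94.2)
acute_renal_failure,M2_D1,ssmix,"(1.2,2.0]",807,241,194,47,80.5% (75.5-85.5)
acute_renal_failure,M2_D1,ssmix,>2.0,640,191,38,153,19.9% (14.2-25.6)
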