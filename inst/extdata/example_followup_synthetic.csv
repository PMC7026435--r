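patient_id,timepoint,euthymic_throughout,hosp_n,suic_att_n,com_pd,bmi,mets,illness_n,scip_cat,pd_x_bd,fast_total,fast_leisure,sf_pf,sf_mh,gaf,n_drugs_cat,antipsychotics,antidepressants,benzodiazepines
P0001,followup,1,2,1,1,31.771126764055115,0,2,severe,1,58,4,-0.8858565255829819,-0.9794047597861881,60,five_plus,1,1,1
P0002,followup,0,2,4,0,34.24283190878355,0,5,mild,1,33,3,-0.058679429081328394,-1.1044057832294703,53,three,1,1,0
P0003,followup,0,1,1,0,31.387362728910592,0,4,severe,1,49,2,0.16151304879459172,-0.4810245588623554,71,three,0,0,1
P0004,followup,0,0,0,0,24.664353486040294,0,1,none,1,6,1,1.6085857592849906,0.1332808457385234,88,two,0,0,0
P0005,followup,1,1,1,1,21.360076505886582,1,3,none,1,30,1,-0.3956564680121354,-0.5980396791730023,70,one,0,1,0
P0006,followup,0,1,0,1,26.181307554731873,0,2,moderate,0,39,1,-0.6189222903885195,-1.2246897073102878,60,two,1,0,1
P0007,followup,0,0,0,0,24.283561266067807,1,3,mild,1,30,1,0.7572460208009455,-1.3947453461557733,69,four,0,1,0
P0008,followup,1,0,0,0,20.75460285648999,0,1,severe,1,33,1,-1.0241910742689724,-0.8178925126388595,61,three,1,0,0
P0009,followup,0,6,2,0,32.388344006023246,1,4,mild,0,40,4,-0.1729341782198538,0.29080446771244417,53,four,1,1,0
P0010,followup,0,0,1,1,24.798333999615863,0,0,mild,1,35,1,-2.1204735026551806,-1.5494905667123815,76,five_plus,0,1,0
P0011,followup,0,0,0,0,21.210000726993883,0,0,none,0,9,0,0.4228379711384766,-0.47283863995620024,94,four,1,0,0
P0012,followup,1,4,0,0,20.84650184062843,1,3,moderate,1,33,6,-0.06942226110946648,-1.073895745039128,71,two,1,1,0
P0013,followup,1,0,0,0,24.637163683258258,0,3,none,1,36,2,-0.0077625503296189224,-0.8525819696408737,56,five_plus,0,1,1
P0014,followup,1,0,1,0,14.972422006466735,1,0,none,0,28,1,0.3130043430074127,-0.269557158725694,97,three,0,0,0
P0015,followup,0,0,3,0,21.554008192594374,0,1,none,0,21,6,-2.0022833414727885,-1.9202786923062032,72,three,1,0,1
P0016,followup,0,0,1,0,28.664927728578185,0,2,severe,0,20,1,-0.6079594659095104,-1.243218534865188,75,two,0,1,1
P0017,followup,1,0,0,0,30.021435672393224,1,2,none,0,25,4,-0.625083997695649,-2.192551991559163,61,five_plus,1,1,1
P0018,followup,1,11,6,1,15.24901269154101,1,3,moderate,1,56,4,-0.4400551960632124,-0.8256346944801161,70,four,1,1,1
P0019,followup,0,0,0,0,20.931801456934924,1,0,none,1,31,2,-1.5421065181966798,-0.327210260952798,47,five_plus,1,0,1
P0020,followup,0,1,0,0,19.735349985040934,0,0,mild,0,2,1,0.5609349911331354,-0.9281952706357319,87,three,1,0,0
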