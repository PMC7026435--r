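patient_id,timepoint,euthymic_throughout,hosp_n,suic_att_n,com_pd,bmi,mets,illness_n,scip_cat,pd_x_bd,fast_total,fast_leisure,sf_pf,sf_mh,gaf,n_drugs_cat,antipsychotics,antidepressants,benzodiazepines
P0001,baseline,1,3,5,0,20.856113107433302,1,1,moderate,1,52,4,-0.3957480916383305,-1.8529079136781585,58,three,1,1,1
P0002,baseline,0,0,1,1,33.29138672684699,1,2,severe,1,38,5,-0.47696913915417816,-0.7171644412441942,41,four,1,1,1
P0003,baseline,0,1,2,0,35.028609735254804,0,4,moderate,1,22,5,0.4162986312778232,-0.25949783140063987,69,four,0,1,1
P0004,baseline,0,2,1,0,23.742082075985,0,0,none,0,20,4,1.1925286213038377,-0.7533862359662087,85,one,1,1,0
P0005,baseline,1,0,4,1,26.86718512231471,1,1,mild,1,37,1,-1.0224686540311874,-0.3739769619612766,61,three,1,0,1
P0006,baseline,0,1,4,0,27.027012204621297,0,3,none,1,29,4,-0.040946480274891395,-0.7561462270270318,55,five_plus,1,1,0
P0007,baseline,0,0,0,0,26.158343944784757,0,2,none,0,11,2,-0.1745991446669331,-0.12316838030073557,80,one,1,0,1
P0008,baseline,1,2,1,1,18.039233920045262,0,1,mild,0,30,4,0.7439848219595253,-1.0289752662613367,62,three,1,0,0
P0009,baseline,0,1,0,0,19.39291246312891,1,3,none,0,34,5,-0.22704295543634195,-0.6158683655131951,52,four,1,1,1
P0010,baseline,0,0,0,0,27.40571511305558,0,0,moderate,0,15,3,0.4868579053766013,-0.22598182098591407,87,two,1,1,0
P0011,baseline,0,0,0,0,18.073188412570083,0,2,none,0,9,0,0.16632934282885542,-1.5089540092069385,63,one,1,1,0
P0012,baseline,1,11,17,1,30.044191223005082,0,2,mild,1,62,5,-1.1804953039386845,-0.7422825935674731,77,five_plus,1,1,1
P0013,baseline,1,2,0,0,22.151436009095573,1,1,moderate,1,35,2,-0.11205009062659282,-1.0992109913416888,87,five_plus,0,0,0
P0014,baseline,1,0,0,0,20.301398130466858,0,0,none,1,10,1,-1.2199382574172284,-0.8673376508202209,75,two,1,1,1
P0015,baseline,0,4,1,1,13.423329746417107,1,2,none,1,32,5,-0.5921789182885064,-0.4969989273217945,79,two,1,1,0
P0016,baseline,0,2,0,0,24.409638642060443,0,3,none,1,30,2,0.21358746758940994,-0.35318961885485933,48,four,1,1,1
P0017,baseline,1,0,0,0,23.78078174855298,1,2,none,1,25,2,0.6588090758307179,-0.397665744093747,81,one,0,0,0
P0018,baseline,1,3,2,1,29.141624092037866,0,0,moderate,1,24,4,-2.5120480823868117,-0.08180186013665303,58,three,1,0,0
P0019,baseline,0,0,1,0,28.320243357970092,0,1,mild,1,30,2,-0.3679046581865698,-1.1782939204271745,62,three,1,1,1
P0020,baseline,0,1,0,0,18.377588282251743,0,0,none,0,6,1,0.49734237036981965,-0.9377331203236211,84,one,0,0,0
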