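donor_protein,donor_terminus,donor_variant,acceptor_protein,acceptor_terminus,acceptor_variant,compartment,mean_E_pct,ci95_halfwidth_pct,n_cells,verdict,value_printed,group
Gts1,N,,Sla2,N,,endocytic_sites,6.7,1.6,,positive,TRUE,green
Gts1,C,,Sla2,N,,endocytic_sites,2.8,1.5,,positive,TRUE,green
Gts1,C,,Sla1,C,,endocytic_sites,8.1,0.9,,positive,TRUE,green
Gts1,N,,Sla1,C,,endocytic_sites,1.2,0.6,,positive,TRUE,green
Gts1,N,,Pan1,N,,endocytic_sites,3.2,,,positive,TRUE,green
Gts1,C,,Pan1,N,,endocytic_sites,3.7,,,positive,TRUE,green
Pan1,N,,Sla2,N,,endocytic_sites,,,,positive,FALSE,green
Sla1,C,,End3,N,,endocytic_sites,4.7,0.8,,positive,TRUE,green
Ent1,C,,Sla1,C,,endocytic_sites,,,,positive,FALSE,green
Ent2,C,,Sla1,C,,endocytic_sites,,,,positive,FALSE,green
Yap1801,C,,Ent1,C,,endocytic_sites,,,,positive,FALSE,green
Yap1802,C,,Ent2,C,,endocytic_sites,,,,positive,FALSE,green
Sla2,C,,End3,C,,endocytic_sites,5.1,1.0,,positive,TRUE,red
Sla1,N,,End3,C,,endocytic_sites,,,,positive,FALSE,red
Pan1,C,,Sla1,N,,endocytic_sites,,,,positive,FALSE,red
Sla1,C,,End3,C,,endocytic_sites,2.8,0.6,,positive,TRUE,cross
Sla2,C,,End3,N,,endocytic_sites,1.9,0.6,,positive,TRUE,cross
End3,N,,Pan1,C,,endocytic_sites,5.2,0.8,30,positive,TRUE,cross
Chc1,C,,Apl1,C,,endocytic_sites,,,,positive,FALSE,clathrin
Chc1,C,,Ent1,C,,endocytic_sites,,,,positive,FALSE,clathrin
Chc1,C,,Ent2,C,,endocytic_sites,,,,positive,FALSE,clathrin
Chc1,C,,End3,C,,endocytic_sites,,,,positive,FALSE,clathrin
Chc1,C,,Sla1,C,,endocytic_sites,,,,positive,FALSE,clathrin
Chc1,C,,Gts1,C,,endocytic_sites,,,,positive,FALSE,clathrin
Chc1,C,,Pan1,N,,endocytic_sites,,,,positive,FALSE,clathrin
Clc1,C,,End3,C,,endocytic_sites,,,,positive,FALSE,clathrin
Pan1,C,,Clc1,C,,endocytic_sites,,,,negative,FALSE,tested_negative
Pan1,C,,Chc1,C,,endocytic_sites,,,,negative,FALSE,tested_negative
Sla2,C,,Clc1,C,,endocytic_sites,,,,negative,FALSE,tested_negative
Sla1,N,,Clc1,C,,endocytic_sites,,,,negative,FALSE,tested_negative
Pan1,N,,Clc1,C,,endocytic_sites,,,,negative,FALSE,tested_negative
Sla2,C,,Pan1,C,,endocytic_sites,,,,negative,FALSE,tested_negative
Pan1,C,1-1050,Clc1,C,,endocytic_sites,,,,positive,FALSE,truncation
Pan1,C,1-1050,Chc1,C,,endocytic_sites,,,,positive,FALSE,truncation
Sla2,C,dTHATCH,Clc1,C,,endocytic_sites,,,,positive,FALSE,truncation
Sla2,C,,Pan1,C,1-1050,endocytic_sites,9.0,0.7,,positive,TRUE,truncation
Sla2,C,,Pan1,C,1-1303,endocytic_sites,4.8,0.5,,positive,TRUE,truncation
Pan1,N,402-1480,Chc1,C,,endocytic_sites,,,,positive,FALSE,truncation
Pan1,N,402-1480,Clc1,C,,endocytic_sites,,,,positive,FALSE,truncation
Syp1,C,,Ede1,C,,endocytic_sites,2.5,0.8,51,positive,TRUE,isolated
Las17,C,,Vrp1,C,,endocytic_sites,,,,positive,FALSE,isolated
Bzz1,C,,Lsb3,C,,endocytic_sites,,,,positive,FALSE,isolated
Sla1,C,,Sla1,C,tandem,endocytic_sites,15.1,1.3,,positive,TRUE,control
Sla2,C,,Sla2,C,tandem,endocytic_sites,18.8,1.4,,positive,TRUE,control
Syp1,C,,Ede1,C,,cytoplasm,2.5,0.6,45,positive,TRUE,table1
End3,N,,Pan1,C,,cytoplasm,4.5,1.3,29,positive,TRUE,table1
Las17,C,,Sla1,C,,cytoplasm,1.5,2.2,13,negative,TRUE,table1
Las17,N,,Sla1,C,,cytoplasm,8.5,1.3,30,positive,TRUE,table1
Las17,N,,Sla1,N,,cytoplasm,9.8,2.9,24,positive,TRUE,table1
Las17,C,,Sla1,C,,endocytic_sites,0.1,0.7,13,negative,TRUE,table1
Las17,N,,Sla1,C,,endocytic_sites,0.0,2.3,31,negative,TRUE,table1
Las17,N,,Sla1,N,,endocytic_sites,0.7,2.5,36,negative,TRUE,table1
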