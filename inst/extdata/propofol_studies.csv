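study_id,label,bolus_mg_kg,bolus_s,rate1_mg_kg_min,dur1_min,rate2_mg_kg_min,dur2_min,body_weight_kg,n_animals,role,auc_pred_ug_h_ml,auc_obs_ug_h_ml
cockshott_1992,"Cockshott et al. (1992)",7,60,0.47,360,NA,NA,17.9,3,development,85.63,80.53
nolan_reid_1993,"Nolan and Reid (1993)",4,60,0.4,60,NA,NA,21.25,7,development,13.81,12.04
luiz_2012,"Luiz (2012)",8,60,0.4,60,NA,NA,10.7,6,development,14.05,14.61
reid_nolan_1996,"Reid and Nolan (1996)",5,60,NA,NA,NA,NA,29,6,development,2.25,2.86
hall_1994,"Hall et al. (1994)",6.9,60,0.4,120,NA,NA,21.5,6,validation,26.93,26.07
hughes_nolan_1999,"Hughes and Nolan (1999)",4,60,0.3,20,0.2,70,25.58,8,validation,10.92,8.87
nolan_reid_grant_1993,"Nolan, Reid and Grant (1993)",6.5,60,NA,NA,NA,NA,29.5,6,validation,2.92,1.56
zoran_1993,"Zoran et al. (1993)",5,60,NA,NA,NA,NA,32.7,10,validation,2.19,1.51
mandsager_1995,"Mandsager et al. (1995)",10,60,0.4,120,NA,NA,25.5,5,validation,25.89,23.93
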