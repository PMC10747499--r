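study,species,route,n_animals,weight_mean_kg,weight_sd_kg,dose_mg,n_doses,interval_h,note
rat_im,rat,im,6,0.241,0.016,2.5,1,NA,single-dose intramuscular
rat_map_single,rat,map,6,0.284,0.010,11.72,1,NA,single-dose patch
rat_map_weekly,rat,map,6,0.198,0.008,11.72,6,168,once-weekly patch; sampling pre-dose and 24 h and 7 d post dose
human_im,human,im,6,NA,NA,800,1,NA,single-dose intramuscular in HIV-negative adults
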