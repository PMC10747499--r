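study,metric,observed,predicted,unit,printed_ratio,printed_aafe
rat_im,AUC_0_28d,1268.1,1431.1,ug*day/mL,1.13,1.13
rat_im,Cmax,74.5,61.1,ug/mL,0.82,1.22
rat_im,C_28d,14.5,20,ug/mL,1.38,1.38
rat_im,Profile,NA,NA,,1.10,NA
rat_map_single,AUC_0_28d,291.1,304.6,ug*day/mL,1.05,1.05
rat_map_single,Cmax,18.1,20.7,ug/mL,1.15,1.15
rat_map_single,C_28d,3.1,3.3,ug/mL,1.06,1.06
rat_map_single,Profile,NA,NA,,NA,1.12
rat_map_weekly,Cmax_first,35.1,28.7,ug/mL,0.82,1.22
rat_map_weekly,Cmax_ss,60.3,67.4,ug/mL,1.12,1.12
rat_map_weekly,C_42d,11.2,17.9,ug/mL,1.60,1.60
rat_map_weekly,Profile,NA,NA,,NA,1.04
human_im,AUC_0_4w,1497,1993.7,ug*h/mL,1.33,1.33
human_im,AUC_0_12w,3851,4792.7,ug*h/mL,1.24,1.24
human_im,Cmax,3.3,3.4,ug/mL,1.02,1.02
human_im,C_4w,2,2.8,ug/mL,1.39,1.39
human_im,Profile,NA,NA,,NA,1.23
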