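table,label,a,b,c,d,printed_or,printed_ci_low,printed_ci_high
1,age_41_45,44,187,11,61,1.31,0.63,2.68
1,age_46_50,106,282,11,61,2.08,1.06,4.11
1,age_ge51,72,169,11,61,2.36,1.18,4.75
1,smoking,40,73,193,626,1.78,1.17,2.70
1,alcohol,41,75,192,624,1.78,1.18,2.69
1,bmi_abnormal,145,277,88,422,2.51,1.85,3.41
1,tg_high,159,171,74,528,6.63,4.79,9.18
1,hdl_low,101,159,132,540,2.60,1.90,3.56
1,ldl_high,39,77,194,622,1.62,1.07,2.47
1,vegetable_51_70,125,263,67,279,1.98,1.41,2.78
1,vegetable_lt50,41,144,67,279,1.19,0.77,1.84
1,creatinine_abnormal,12,17,221,536,1.71,0.80,3.65
1,urine_protein,8,13,208,513,1.52,0.62,3.72
1,diabetes,12,13,221,686,2.86,1.29,6.37
1,thyroid,3,6,230,693,1.51,0.37,6.07
2,genotype_tt,73,198,160,501,1.15,0.84,1.59
3,sodium_high,51,78,182,621,2.23,1.51,3.29
4,joint_e,32,55,128,446,2.03,1.26,3.27
4,joint_g,54,175,128,446,1.08,0.75,1.55
4,joint_ge,19,23,128,446,2.88,1.52,5.45
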