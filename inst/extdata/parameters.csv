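name,mean,family,ci_low,ci_high
cost_screen_mms_dropout,54,beta,33,74
cost_screen_mms_complete,61,hybrid,37,83
cost_screen_uss_dropout,56,gamma,29,92
cost_screen_uss_complete,61,hybrid,31,100
cost_invitation,2.09,gamma,1.70,2.52
cost_diag_borderline,110,gamma,91,135
cost_diag_stage1,116,gamma,90,133
cost_diag_stage2,126,gamma,94,140
cost_diag_stage3,126,gamma,102,152
cost_diag_stage4,112,gamma,102,152
cost_treat_borderline,3000,gamma,1161,5696
cost_treat_stage1,6961,gamma,4856,9438
cost_treat_stage2,7325,gamma,5211,9795
cost_treat_stage3,9016,gamma,6866,11454
cost_treat_stage4,5892,gamma,3823,8402
cost_end_of_life,7080,gamma,5761,8533
utility_cancer_free,0.900,beta,0.325,1
disutility_stage1_or_fp,0.200,beta,0.044,0.437
disutility_stage2,0.325,beta,0.214,0.534
disutility_stage3,0.413,beta,0.329,0.600
disutility_stage4,0.455,beta,0.413,0.601
fp_per_cancer_mms,2.302,beta,2.188,2.412
fp_per_cancer_uss,9.963,beta,9.813,10.104
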