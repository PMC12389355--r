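victim,perpetrator,perp_dose_mg,perp_n_doses,perp_interval_h,victim_dose_mg,victim_offset_h
midazolam,rifampicin,600,5,24,3,97
alfentanil,rifampicin,600,5,24,4,97
atorvastatin,rifampicin,600,5,24,40,97
omeprazole,rifampicin,450,6,24,20,121
pioglitazone,rifampicin,600,6,24,30,97
tolbutamide,rifampicin,600,14,24,500,313
glyburide,rifampicin,600,5,24,1.75,108.5
bupropion,rifampicin,600,10,24,150,156
repaglinide,rifampicin,600,10,24,0.5,228.5
warfarin,rifampicin,600,3,24,105,96
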