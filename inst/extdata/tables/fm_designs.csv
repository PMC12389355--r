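victim,enzyme,fm,source
midazolam,CYP3A4,0.94,design
alfentanil,CYP3A4,0.90,design
atorvastatin,CYP3A4,0.90,design
omeprazole,CYP2C19,0.68,design
omeprazole,CYP3A4,0.32,design
pioglitazone,CYP2C8,0.56,design
pioglitazone,CYP3A4,0.37,design
tolbutamide,CYP2C9,0.85,design
tolbutamide,other,0.15,design
glyburide,CYP3A4,0.53,design
glyburide,CYP2C9,0.35,design
glyburide,CYP2C8,0.12,design
bupropion,CYP2B6,0.21,design
bupropion,CYP2C19,0.18,design
bupropion,CYP3A4,0.10,fixture
repaglinide,CYP3A4,0.74,design
repaglinide,CYP2C8,0.26,design
warfarin,CYP2C9,0.64,design
warfarin,CYP3A4,0.05,design
warfarin,CYP2B6,0.12,design
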