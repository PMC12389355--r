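compound,enzyme,donor,ec50_uM,emax_fold,nc
apalutamide,CYP3A4,1,0.690,6.12,FALSE
apalutamide,CYP3A4,2,1.61,20.8,FALSE
apalutamide,CYP3A4,3,1.08,7.45,FALSE
carbamazepine,CYP3A4,1,23.6,4.09,FALSE
carbamazepine,CYP3A4,2,61.2,9.93,FALSE
carbamazepine,CYP3A4,3,28.5,3.53,FALSE
efavirenz,CYP3A4,1,2.61,5.32,FALSE
efavirenz,CYP3A4,2,4.38,11.3,FALSE
efavirenz,CYP3A4,3,3.04,5.31,FALSE
rifampicin,CYP3A4,1,0.0655,5.60,FALSE
rifampicin,CYP3A4,2,0.128,13.4,FALSE
rifampicin,CYP3A4,3,0.0602,4.87,FALSE
apalutamide,CYP2C8,1,1.68,8.36,FALSE
apalutamide,CYP2C8,2,1.22,4.55,FALSE
apalutamide,CYP2C8,3,1.26,7.20,FALSE
carbamazepine,CYP2C8,1,35.6,3.21,FALSE
carbamazepine,CYP2C8,2,20.0,2.26,FALSE
carbamazepine,CYP2C8,3,40.2,5.07,FALSE
efavirenz,CYP2C8,1,4.48,5.22,FALSE
efavirenz,CYP2C8,2,1.97,2.85,FALSE
efavirenz,CYP2C8,3,2.95,5.11,FALSE
rifampicin,CYP2C8,1,0.504,6.89,FALSE
rifampicin,CYP2C8,2,0.260,4.51,FALSE
rifampicin,CYP2C8,3,0.307,7.36,FALSE
apalutamide,CYP2C9,1,0.794,3.50,FALSE
apalutamide,CYP2C9,2,0.419,3.63,FALSE
apalutamide,CYP2C9,3,0.474,2.73,FALSE
carbamazepine,CYP2C9,1,9.86,2.44,FALSE
carbamazepine,CYP2C9,2,NA,NA,TRUE
carbamazepine,CYP2C9,3,NA,NA,TRUE
efavirenz,CYP2C9,1,0.455,2.46,FALSE
efavirenz,CYP2C9,2,NA,NA,TRUE
efavirenz,CYP2C9,3,NA,NA,TRUE
rifampicin,CYP2C9,1,0.0876,3.23,FALSE
rifampicin,CYP2C9,2,0.0784,2.87,FALSE
rifampicin,CYP2C9,3,0.149,2.57,FALSE
apalutamide,CYP2C19,1,4.01,8.42,FALSE
apalutamide,CYP2C19,2,5.22,7.70,FALSE
apalutamide,CYP2C19,3,6.04,14.6,FALSE
carbamazepine,CYP2C19,1,124,5.11,FALSE
carbamazepine,CYP2C19,2,186,4.48,FALSE
carbamazepine,CYP2C19,3,182,7.22,FALSE
efavirenz,CYP2C19,1,8.30,4.79,FALSE
efavirenz,CYP2C19,2,NA,NA,TRUE
efavirenz,CYP2C19,3,2.91,3.56,FALSE
rifampicin,CYP2C19,1,1.64,19.9,FALSE
rifampicin,CYP2C19,2,0.803,8.45,FALSE
rifampicin,CYP2C19,3,1.47,17.9,FALSE
apalutamide,CYP2B6,1,4.44,10.2,FALSE
apalutamide,CYP2B6,2,2.98,6.71,FALSE
apalutamide,CYP2B6,3,2.96,9.06,FALSE
carbamazepine,CYP2B6,1,46.9,5.74,FALSE
carbamazepine,CYP2B6,2,41.9,4.84,FALSE
carbamazepine,CYP2B6,3,59.0,6.93,FALSE
efavirenz,CYP2B6,1,2.76,6.46,FALSE
efavirenz,CYP2B6,2,3.67,6.61,FALSE
efavirenz,CYP2B6,3,4.01,9.44,FALSE
rifampicin,CYP2B6,1,0.415,6.71,FALSE
rifampicin,CYP2B6,2,0.53,5.91,FALSE
rifampicin,CYP2B6,3,0.399,8.44,FALSE
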