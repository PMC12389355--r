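compound,enzyme,donor,ec50_uM,emax_fold,nc
apalutamide,CYP3A4,1,0.686,2.96,FALSE
apalutamide,CYP3A4,2,0.709,3.03,FALSE
apalutamide,CYP3A4,3,1.50,10.6,FALSE
carbamazepine,CYP3A4,1,6.40,2.31,FALSE
carbamazepine,CYP3A4,2,2.70,3.38,FALSE
carbamazepine,CYP3A4,3,17.8,4.44,FALSE
efavirenz,CYP3A4,1,1.43,5.07,FALSE
efavirenz,CYP3A4,2,0.259,2.79,FALSE
efavirenz,CYP3A4,3,4.54,16.3,FALSE
rifampicin,CYP3A4,1,0.0509,2.84,FALSE
rifampicin,CYP3A4,2,0.0652,3.45,FALSE
rifampicin,CYP3A4,3,0.0897,7.74,FALSE
apalutamide,CYP2C9,1,13.1,2.79,FALSE
apalutamide,CYP2C9,2,NA,NA,TRUE
apalutamide,CYP2C9,3,23.7,3.25,FALSE
carbamazepine,CYP2C9,1,41.4,2.52,FALSE
carbamazepine,CYP2C9,2,NA,NA,TRUE
carbamazepine,CYP2C9,3,NA,NA,TRUE
efavirenz,CYP2C9,1,4.29,2.40,FALSE
efavirenz,CYP2C9,2,NA,NA,TRUE
efavirenz,CYP2C9,3,NA,NA,TRUE
rifampicin,CYP2C9,1,0.469,2.44,FALSE
rifampicin,CYP2C9,2,NA,NA,TRUE
rifampicin,CYP2C9,3,NA,NA,TRUE
apalutamide,CYP2C19,1,0.455,3.38,FALSE
apalutamide,CYP2C19,2,1.03,3.62,FALSE
apalutamide,CYP2C19,3,0.865,9.66,FALSE
carbamazepine,CYP2C19,1,8.14,2.48,FALSE
carbamazepine,CYP2C19,2,2.05,3.63,FALSE
carbamazepine,CYP2C19,3,18,4.54,FALSE
efavirenz,CYP2C19,1,0.946,3.04,FALSE
efavirenz,CYP2C19,2,0.297,3.52,FALSE
efavirenz,CYP2C19,3,2.48,6.87,FALSE
rifampicin,CYP2C19,1,0.0438,3.48,FALSE
rifampicin,CYP2C19,2,0.0816,4.09,FALSE
rifampicin,CYP2C19,3,0.105,9.32,FALSE
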