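taxon,covariate,beta1,beta1_se,beta2,beta2_se,cov_mean,cov_sd,phi,phi_se,sigma2_proc,sigma2_se,logL,n_years,delta_aicc
Aphanizomenon spp.,temp,0.15,0.11,0.20,0.10,10.33,0.75,-0.10,0.23,0.11,0.04,-12.59,24,0.86
Chaetoceros spp.,DIP,-0.05,0.13,-0.27,0.11,0.74,0.16,-0.09,0.29,0.15,0.07,-22.47,24,1.84
Chaetoceros spp.,strat,-0.14,0.13,0.23,0.12,0.25,0.08,-0.23,0.29,0.16,0.08,-22.90,24,0.98
Dinobryon faculiferum,sal,-0.15,0.20,0.49,0.20,5.45,0.28,0.48,0.23,0.51,0.23,-30.92,23,3.08
Dinobryon faculiferum,temp,0.17,0.26,-0.60,0.24,5.50,1.03,0.53,0.23,0.54,0.24,-31.19,23,2.54
Dinophysis acuminata,temp,0.10,0.09,0.17,0.09,5.44,0.76,0.08,0.28,0.06,0.03,-9.09,24,0.03
Ebria tripartita,strat,0.02,0.15,-0.32,0.14,1.14,0.25,0.56,0.21,0.31,0.11,-24.40,24,1.93
Eutreptiella spp.,temp,-0.23,0.10,0.69,0.10,8.49,0.85,-0.04,0.14,0.07,0.04,-13.45,24,21.7
Hemiselmis spp.,strat,-0.56,0.25,-0.33,0.16,1.44,0.48,0.60,0.19,0.35,0.13,-25.64,24,1.39
Heterocapsa rotundata,sal,-0.18,0.15,0.29,0.14,5.53,0.22,-0.15,0.24,0.30,0.11,-22.51,24,1.26
Heterocapsa triquetra,temp,0.31,0.32,-0.59,0.32,13.77,0.78,-0.16,0.21,1.57,0.47,-39.49,23,0.49
Mesodinium rubrum,sal,0.61,0.28,-0.22,0.13,5.40,0.27,0.45,0.19,0.23,0.11,-25.68,24,0.02
Protoperidinium bipes,sal,-0.08,0.13,0.45,0.12,5.61,0.29,0.46,0.22,0.12,0.08,-20.60,24,8.32
Pseudopedinella spp.,sal,0.10,0.13,-0.32,0.11,5.42,0.25,0.67,0.19,0.18,0.09,-18.26,24,4.95
Snowella spp.,strat,-1.06,0.44,-0.58,0.25,1.30,0.45,0.37,0.24,0.70,0.30,-35.22,24,2.59
Snowella spp.,temp,-0.84,0.45,-0.54,0.23,16.64,1.03,0.38,0.24,0.62,0.29,-35.23,24,2.57
Teleaulax spp.,sal,-0.03,0.12,0.19,0.11,5.53,0.22,0.44,0.21,0.19,0.06,-15.96,24,0.44
Teleaulax spp.,strat,-0.07,0.11,-0.19,0.11,1.41,0.47,0.39,0.22,0.19,0.06,-16.09,24,0.19
Thalassiosira baltica,ice,-0.28,0.15,-0.54,0.14,35.80,35.11,-0.14,0.21,0.13,0.09,-22.03,24,9.61
Woronichinia spp.,strat,-0.59,0.36,-0.63,0.32,0.88,0.39,0.38,0.24,1.24,0.44,-40.04,24,1.26
Woronichinia spp.,temp,-1.02,0.39,0.68,0.34,15.63,0.95,0.27,0.23,1.20,0.43,-40.08,24,1.19
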