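class,taxon,bm_pct,n,median_day,temp_mean,temp_se,sal_mean,sal_se,strat_mean,strat_se
Chlorophyceae,Monoraphidium contortum,1.15,936,163,6.00,0.21,5.42,0.06,0.59,0.04
Chlorophyceae,Oocystis spp.,0.24,1089,238,16.24,0.24,5.53,0.05,1.42,0.10
Chlorophyceae,Planctonema lauterbornii,0.09,1067,280,16.04,0.19,5.47,0.06,0.96,0.10
Chrysophyceae,Dinobryon faculiferum,0.09,1067,157,5.50,0.22,5.45,0.07,0.55,0.04
Chrysophyceae,Pseudopedinella spp.,1.56,987,187,8.49,0.18,5.42,0.06,0.80,0.04
Ciliate,Mesodinium rubrum,11.05,1089,156,5.41,0.21,5.40,0.06,0.55,0.04
Cryptophyceae,Hemiselmis spp.,0.32,1086,233,16.12,0.24,5.52,0.05,1.44,0.10
Cryptophyceae,Plagioselmis prolonga,1.48,1083,228,15.86,0.23,5.50,0.05,1.42,0.10
Cryptophyceae,Teleaulax spp.,1.38,1083,239,16.29,0.24,5.53,0.05,1.41,0.10
Cyanophyceae,Aphanizomenon spp.,29.82,1089,197,10.33,0.17,5.45,0.06,0.99,0.04
Cyanophyceae,Dolichospermum spp.,3.69,1089,197,10.33,0.17,5.45,0.06,0.99,0.04
Cyanophyceae,Nodularia spp.,6.73,1089,208,13.23,0.18,5.52,0.05,1.25,0.06
Cyanophyceae,Planktolyngbya spp.,0.25,1078,260,16.67,0.23,5.57,0.05,1.25,0.10
Cyanophyceae,Snowella spp.,0.73,1089,252,16.64,0.23,5.59,0.05,1.30,0.10
Cyanophyceae,Woronichinia spp.,0.37,1089,284,15.63,0.22,5.47,0.06,0.88,0.09
Diatomophyceae,Chaetoceros spp.,2.18,1089,117,1.37,0.15,5.65,0.07,0.25,0.02
Diatomophyceae,Skeletonema marinoi,2.31,1089,114,1.27,0.15,5.66,0.07,0.26,0.02
Diatomophyceae,Thalassiosira baltica,3.23,1089,116,1.33,0.15,5.65,0.07,0.25,0.02
Dinophyceae,Amphidinium crassum,0.28,1089,188,8.61,0.18,5.43,0.06,0.81,0.04
Dinophyceae,Dinophysis acuminata,3.86,1089,198,10.65,0.17,5.44,0.06,1.01,0.04
Dinophyceae,Heterocapsa rotundata,0.78,1089,239,16.29,0.24,5.53,0.05,1.41,0.10
Dinophyceae,Heterocapsa triquetra,7.21,1067,211,13.77,0.19,5.54,0.05,1.29,0.07
Dinophyceae,Peridiniella catenata,11.52,1089,123,1.53,0.16,5.62,0.07,0.26,0.02
Dinophyceae,Protoperidinium bipes,0.46,1089,126,1.70,0.17,5.61,0.07,0.26,0.02
Dinophyceae,Protoperidinium brevipes,0.67,1056,161,5.84,0.22,5.45,0.07,0.58,0.04
Ebriidea,Ebria tripartita,1.19,1038,203,11.84,0.17,5.47,0.06,1.14,0.06
Euglenophyceae,Eutreptiella spp.,1.26,1089,187,8.49,0.18,5.42,0.06,0.80,0.04
Incertae sedis,Katablepharis spp.,0.32,1089,148,4.43,0.21,5.44,0.07,0.46,0.04
Incertae sedis,Telonema subtile,0.05,1089,197,10.33,0.17,5.45,0.06,0.99,0.04
Prasinophyceae,Pyramimonas spp.,2.61,1089,201,11.30,0.18,5.44,0.06,1.09,0.05
Prymnesiophyceae,Chrysochromulina spp.,3.96,1035,208,13.23,0.18,5.52,0.05,1.25,0.06
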