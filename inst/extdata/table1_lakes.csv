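lake_id,category,substrate,has_glacier,dist_coast_m,lc_ratio,fsc_june,mean_ndvi_summer,droppings,droppings_se,sed_d13c,sed_d13c_se,sed_d15n,sed_d15n_se,sed_afdm_pct,sed_afdm_se,sed_n_pct,sed_n_se,soil_d13c,soil_d13c_se,soil_d15n,soil_d15n_se,soil_afdm_pct,soil_afdm_se,soil_n_pct,soil_n_se
1,muddy_coastal,muddy,FALSE,25,0.18,0.00,0.33,4.0,0.0,-22.2,0.5,8.2,0.4,4.4,0.4,0.42,0.03,-24.5,0.4,2.2,0.9,1.0,0.2,0.04,0.02
2,sandy_coastal,sandy,FALSE,90,0.24,0.12,0.46,3.3,0.3,-22.2,0.4,3.7,0.3,1.9,0.3,0.05,0.01,-25.4,0.3,2.2,0.6,4.6,1.1,0.28,0.11
3,muddy_coastal,muddy,FALSE,100,0.07,0.08,0.29,4.0,0.0,-24.3,0.3,5.5,0.7,19.2,4.0,0.76,0.13,-25.7,0.2,4.6,1.3,17.8,5.6,0.76,0.30
4,muddy_coastal,muddy,FALSE,120,0.02,0.10,0.14,2.0,0.0,-17.1,0.2,2.1,0.1,19.6,4.6,0.96,0.34,-25.8,0.2,3.9,0.3,3.7,1.6,0.27,0.11
5,sandy_coastal,sandy,FALSE,130,0.05,0.03,0.24,2.3,0.3,-24.8,0.3,3.5,0.4,6.8,0.5,0.19,0.03,-25.7,0.2,3.0,0.5,4.1,1.0,0.34,0.16
6,sandy_coastal,sandy,FALSE,150,0.08,0.23,0.18,2.0,0.0,-20.9,0.2,3.3,0.1,5.3,0.7,0.23,0.03,-25.6,0.4,2.4,0.6,2.2,0.6,0.14,0.04
7,muddy_coastal,muddy,FALSE,165,0.05,0.23,0.23,3.3,0.3,-22.6,0.4,3.2,0.3,1.5,0.1,0.25,0.01,-24.9,0.3,1.7,0.6,2.5,1.0,0.11,0.04
8,muddy_coastal,muddy,FALSE,240,0.07,0.00,0.25,4.0,0.0,-25.7,0.2,4.1,0.4,17.2,1.9,0.55,0.12,-25.5,0.1,4.0,1.0,12.4,1.4,0.25,0.06
9,lowland,NA,FALSE,515,0.06,0.41,0.18,1.3,0.3,-23.5,0.5,1.4,0.3,10.3,2.9,0.39,0.11,-25.9,0.1,2.7,0.3,8.3,2.0,0.37,0.11
10,lowland,NA,FALSE,590,0.24,0.10,0.25,1.3,0.3,-17.9,0.3,1.7,0.4,23.2,7.7,0.97,0.25,-25.0,0.3,3.0,0.2,4.1,0.6,0.19,0.04
11,lowland,NA,FALSE,600,0.09,0.16,0.09,1.3,0.3,-24.6,0.2,2.6,0.3,16.5,6.0,0.40,0.07,-25.6,0.1,2.5,0.5,3.4,0.6,0.18,0.03
12,lowland,NA,FALSE,640,0.04,0.86,0.07,1.3,0.3,-25.0,0.1,4.0,1.1,8.9,1.4,0.19,0.03,-25.1,0.3,1.6,0.2,6.7,1.5,0.11,0.03
13,lowland,NA,FALSE,1260,0.11,0.85,0.05,1.7,0.3,-25.8,0.1,2.2,0.1,7.4,1.7,0.12,0.02,-25.9,0.7,2.4,0.4,6.5,1.7,0.20,0.05
14,lowland,NA,FALSE,1440,0.27,0.51,0.04,1.0,0.0,-19.7,1.2,3.8,1.2,8.8,3.7,0.38,0.12,-25.2,0.2,2.7,0.2,3.9,0.5,0.14,0.02
15,glacier,NA,TRUE,1630,0.04,0.59,0.01,2.0,0.0,-22.9,0.2,2.5,0.3,2.8,0.4,0.08,0.02,-24.7,0.3,3.1,0.4,2.6,0.4,0.09,0.02
16,glacier,NA,TRUE,1690,0.19,0.98,-0.13,0.0,0.0,-22.7,0.2,2.1,0.4,1.0,0.1,0.01,0.00,-22.8,0.3,-0.9,0.6,0.8,0.2,0.01,0.00
17,glacier,NA,TRUE,1740,0.14,0.62,0.01,0.0,0.0,-24.6,0.9,1.2,1.1,3.6,0.8,0.09,0.03,-25.9,0.1,2.1,0.6,1.8,0.1,0.13,0.02
18,glacier,NA,TRUE,2200,0.01,0.90,-0.08,0.0,0.0,-24.8,0.1,0.4,0.5,2.4,0.2,0.04,0.00,-25.1,0.2,1.2,0.6,1.4,0.1,0.09,0.01
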