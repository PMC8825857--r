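field,l1,l2,l3,l4,l5,l6,l7,l8,l9,l10,l11,l12,l13,l14,l15,l16,l17,l18
category,M,S,M,M,S,S,M,M,L,L,L,L,L,L,G,G,G,G
dist,25,90,100,120,130,150,165,240,515,590,600,640,1260,1440,1630,1690,1740,2200
lc,0.18,0.24,0.07,0.02,0.05,0.08,0.05,0.07,0.06,0.24,0.09,0.04,0.11,0.27,0.04,0.19,0.14,0.01
fsc,0.00,0.12,0.08,0.10,0.03,0.23,0.23,0.00,0.41,0.10,0.16,0.86,0.85,0.51,0.59,0.98,0.62,0.90
ndvi,0.33,0.46,0.29,0.14,0.24,0.18,0.23,0.25,0.18,0.25,0.09,0.07,0.05,0.04,0.01,-0.13,0.01,-0.08
droppings,4.0,3.3,4.0,2.0,2.3,2.0,3.3,4.0,1.3,1.3,1.3,1.3,1.7,1.0,2.0,0.0,0.0,0.0
sed_d13c,-22.2,-22.2,-24.3,-17.1,-24.8,-20.9,-22.6,-25.7,-23.5,-17.9,-24.6,-25.0,-25.8,-19.7,-22.9,-22.7,-24.6,-24.8
sed_d15n,8.2,3.7,5.5,2.1,3.5,3.3,3.2,4.1,1.4,1.7,2.6,4.0,2.2,3.8,2.5,2.1,1.2,0.4
sed_afdm,4.4,1.9,19.2,19.6,6.8,5.3,1.5,17.2,10.3,23.2,16.5,8.9,7.4,8.8,2.8,1.0,3.6,2.4
sed_n,0.42,0.05,0.76,0.96,0.19,0.23,0.25,0.55,0.39,0.97,0.40,0.19,0.12,0.38,0.08,0.01,0.09,0.04
soil_d13c,-24.5,-25.4,-25.7,-25.8,-25.7,-25.6,-24.9,-25.5,-25.9,-25.0,-25.6,-25.1,-25.9,-25.2,-24.7,-22.8,-25.9,-25.1
soil_d15n,2.2,2.2,4.6,3.9,3.0,2.4,1.7,4.0,2.7,3.0,2.5,1.6,2.4,2.7,3.1,-0.9,2.1,1.2
soil_afdm,1.0,4.6,17.8,3.7,4.1,2.2,2.5,12.4,8.3,4.1,3.4,6.7,6.5,3.9,2.6,0.8,1.8,1.4
soil_n,0.04,0.28,0.76,0.27,0.34,0.14,0.11,0.25,0.37,0.19,0.18,0.11,0.20,0.14,0.09,0.01,0.13,0.09
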