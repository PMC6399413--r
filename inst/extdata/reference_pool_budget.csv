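pool,c_mass_g,c_mass_se,excess_13c_mg,excess_13c_se,pct_13c,pct_13c_se,n_mass_g,n_mass_se,excess_15n_ug,excess_15n_se,pct_15n,pct_15n_se,cn,cn_se
leaves,0.49,0.05,4.4,0.64,20.86,2.74,0.03,0.00,0.32,0.14,0.10,0.05,19.01,0.49
stem,2.07,0.19,7.41,0.48,35.92,2.21,0.03,0.00,3.72,1.73,1.21,0.58,62.74,4.09
roots,0.88,0.14,6.57,0.74,31.47,3.04,0.02,0.00,16.11,4.66,5.71,1.99,36.98,1.37
plant_biomass,3.44,0.31,18.37,1.10,88.26,1.35,0.08,0.01,20.15,5.09,7.02,2.12,NA,NA
rhizosphere_soil,6.70,1.29,0.96,0.22,4.35,0.76,0.53,0.10,13.22,3.41,4.25,1.12,12.46,0.14
bulk_soil,25.64,1.88,1.52,0.34,7.04,1.25,2.05,0.16,35.77,13.48,10.25,3.07,12.51,0.06
litter,6.23,0.15,0.08,0.03,0.36,0.13,0.24,0.00,250.48,18.46,78.48,3.56,25.7,0.39
soil_litter,38.57,1.72,2.56,0.43,11.74,1.35,2.83,0.13,299.46,26.07,92.98,2.12,NA,NA
total,42.01,1.88,20.93,1.48,100,NA,2.91,0.14,319.62,8.47,100,NA,NA,NA
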