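study,drug,dose,dose_units,age_min_y,age_max_y,parameter,units,reference_predicted,reference_predicted_sd,observed,observed_sd
theophylline_neonates_0_0p02y,theophylline,4,mg/kg,0,0.02,Cmax,mg/L,7.31,2.26,4.62,NA
theophylline_neonates_0_0p02y,theophylline,4,mg/kg,0,0.02,CL,mL/h/kg,24.39,8.60,25.00,6.00
theophylline_neonates_0_0p02y,theophylline,4,mg/kg,0,0.02,AUC,mg.h/L,181.72,56.11,124.90,NA
theophylline_neonates_0p02_0p07y,theophylline,4,mg/kg,0.02,0.07,Cmax,mg/L,7.30,2.26,5.07,NA
theophylline_neonates_0p02_0p07y,theophylline,4,mg/kg,0.02,0.07,CL,mL/h/kg,26.53,10.18,31.00,5.00
theophylline_neonates_0p02_0p07y,theophylline,4,mg/kg,0.02,0.07,AUC,mg.h/L,167.08,51.33,115.80,NA
theophylline_children_6p6_12p25y,theophylline,3.94,mg/kg,6.6,12.25,Cmax,mg/L,8.51,2.58,NA,NA
theophylline_children_6p6_12p25y,theophylline,3.94,mg/kg,6.6,12.25,CL,mL/h/kg,78.90,30.95,74.00,20.00
theophylline_children_6p6_12p25y,theophylline,3.94,mg/kg,6.6,12.25,AUC,mg.h/L,54.38,16.86,NA,NA
theophylline_neonates_0_0p07y,theophylline,4,mg/kg,0,0.07,Cmax,mg/L,7.31,2.25,4.83,NA
theophylline_neonates_0_0p07y,theophylline,4,mg/kg,0,0.07,CL,mL/h/kg,26.08,7.56,30.00,5.00
theophylline_neonates_0_0p07y,theophylline,4,mg/kg,0,0.07,AUC,mg.h/L,169.61,52.27,116.80,NA
fentanyl_children_8_13y,fentanyl,5,ug/kg,8,13,Cmax,ng/mL,22.73,2.41,NA,NA
fentanyl_children_8_13y,fentanyl,5,ug/kg,8,13,CL,mL/h/kg,1146.71,248.98,756.00,168.00
fentanyl_children_8_13y,fentanyl,5,ug/kg,8,13,AUC,ng.h/mL,4.35,0.61,NA,NA
fentanyl_children_6_16y,fentanyl,4,ug/kg,6,16,Cmax,ng/mL,18.81,2.74,NA,NA
fentanyl_children_6_16y,fentanyl,4,ug/kg,6,16,CL,mL/h/kg,1096.58,346.95,756.00,168.80
fentanyl_children_6_16y,fentanyl,4,ug/kg,6,16,AUC,ng.h/mL,3.62,0.55,NA,NA
ceftazidime_infants_0p1_2y,ceftazidime,50,mg/kg,0.1,2,Cmax,mg/L,188.38,9.70,NA,NA
ceftazidime_infants_0p1_2y,ceftazidime,50,mg/kg,0.1,2,CL,mL/h/kg,150.17,48.64,170.00,NA
ceftazidime_infants_0p1_2y,ceftazidime,50,mg/kg,0.1,2,AUC,mg.h/L,346.06,64.27,NA,NA
vancomycin_children_0p08_14y,vancomycin,39.99,mg/kg/d,0.08,14,Cmax,mg/L,29.57,3.27,NA,NA
vancomycin_children_0p08_14y,vancomycin,39.99,mg/kg/d,0.08,14,CL,mL/h/kg,122.47,53.59,109.74,43.68
vancomycin_children_0p08_14y,vancomycin,39.99,mg/kg/d,0.08,14,AUC,mg.h/L,307.99,57.96,175.34,157.86
vancomycin_infants_0p09_2y,vancomycin,39.8,mg/kg/d,0.09,2,Cmax,mg/L,31.65,2.72,NA,NA
vancomycin_infants_0p09_2y,vancomycin,39.8,mg/kg/d,0.09,2,CL,mL/h/kg,129.65,45.68,200.00,100.00
vancomycin_infants_0p09_2y,vancomycin,39.8,mg/kg/d,0.09,2,AUC,mg.h/L,306.15,57.15,261.40,105.10
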