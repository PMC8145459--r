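band,sex,age_lo,age_hi,parameter,n,mean,sd,p2_5,p97_5
lt11,male,9,11,height_cm,1660,138.72,8.25,122.40,155.00
lt11,female,9,11,height_cm,1798,138.64,8.26,122.10,155.00
lt11,male,9,11,weight_kg,1660,34.03,8.46,23.05,56.89
lt11,female,9,11,weight_kg,1800,32.68,7.51,22.20,51.99
lt11,male,9,11,bmi_kg_m2,1657,17.50,3.02,13.71,25.49
lt11,female,9,11,bmi_kg_m2,1798,16.84,2.56,13.34,23.73
lt11,male,9,11,heart_rate_bpm,1612,90.58,14.25,64.00,123.00
lt11,female,9,11,heart_rate_bpm,1771,94.45,14.28,68.00,125.00
lt11,male,9,11,creatinine_umol_L,592,52.11,11.49,35.00,77.00
lt11,female,9,11,creatinine_umol_L,589,50.19,11.75,33.00,75.25
lt11,male,9,11,albumin_g_L,592,47.96,2.66,43.10,53.22
lt11,female,9,11,albumin_g_L,589,47.65,2.62,43.00,53.58
lt11,male,9,11,hematocrit_pct,1377,40.85,2.44,36.44,46.00
lt11,female,9,11,hematocrit_pct,1488,40.97,2.42,36.20,45.80
11-12,male,11,12,height_cm,3577,147.67,9.15,131.04,167.00
11-12,female,11,12,height_cm,3522,148.56,7.96,132.31,163.00
11-12,male,11,12,weight_kg,3583,40.60,10.59,26.70,67.08
11-12,female,11,12,weight_kg,3532,40.32,9.04,26.20,62.00
11-12,male,11,12,bmi_kg_m2,3576,18.40,3.31,14.01,26.59
11-12,female,11,12,bmi_kg_m2,3522,18.11,2.93,13.84,25.41
11-12,male,11,12,heart_rate_bpm,3524,90.36,14.36,65.00,120.00
11-12,female,11,12,heart_rate_bpm,3466,94.48,14.99,68.00,127.00
11-12,male,11,12,creatinine_umol_L,1426,56.62,11.91,37.00,79.00
11-12,female,11,12,creatinine_umol_L,1434,52.56,11.30,34.00,75.00
11-12,male,11,12,albumin_g_L,1427,47.86,2.89,42.77,54.00
11-12,female,11,12,albumin_g_L,1433,47.90,2.86,42.90,54.10
11-12,male,11,12,hematocrit_pct,3040,41.96,2.58,37.00,47.30
11-12,female,11,12,hematocrit_pct,2973,41.83,2.47,37.00,46.50
13-14,male,13,14,height_cm,3696,159.31,9.49,139.89,176.00
13-14,female,13,14,height_cm,3854,155.27,6.45,142.00,167.76
13-14,male,13,14,weight_kg,3701,49.38,11.73,31.76,79.22
13-14,female,13,14,weight_kg,3856,47.37,8.12,33.40,66.50
13-14,male,13,14,bmi_kg_m2,3695,19.27,3.25,15.05,28.33
13-14,female,13,14,bmi_kg_m2,3853,19.58,2.74,15.19,26.34
13-14,male,13,14,heart_rate_bpm,3662,84.00,13.40,60.58,113.00
13-14,female,13,14,heart_rate_bpm,3819,89.38,13.99,66.00,121.00
13-14,male,13,14,creatinine_umol_L,1718,62.32,14.03,39.00,93.00
13-14,female,13,14,creatinine_umol_L,1756,55.84,12.27,37.00,82.00
13-14,male,13,14,albumin_g_L,1718,48.20,3.21,42.30,55.00
13-14,female,13,14,albumin_g_L,1753,48.29,3.17,42.38,55.10
13-14,male,13,14,hematocrit_pct,2962,43.87,2.86,38.10,49.50
13-14,female,13,14,hematocrit_pct,3195,41.95,2.72,36.39,47.20
15-16,male,15,16,height_cm,3675,167.76,7.38,152.00,181.00
15-16,female,15,16,height_cm,4688,157.70,5.80,146.40,169.00
15-16,male,15,16,weight_kg,3679,57.28,11.61,40.50,88.40
15-16,female,15,16,weight_kg,4696,51.62,7.69,40.00,70.00
15-16,male,15,16,bmi_kg_m2,3675,20.27,3.38,15.94,29.91
15-16,female,15,16,bmi_kg_m2,4688,20.74,2.74,16.40,27.11
15-16,male,15,16,heart_rate_bpm,3639,78.94,13.42,56.00,109.00
15-16,female,15,16,heart_rate_bpm,4658,85.31,13.49,62.00,115.00
15-16,male,15,16,creatinine_umol_L,1672,73.34,13.80,48.00,102.00
15-16,female,15,16,creatinine_umol_L,1897,60.85,12.15,41.00,85.00
15-16,male,15,16,albumin_g_L,1671,49.25,3.29,43.48,56.20
15-16,female,15,16,albumin_g_L,1891,48.94,3.26,43.10,56.27
15-16,male,15,16,hematocrit_pct,3300,46.02,2.94,39.50,51.40
15-16,female,15,16,hematocrit_pct,4161,41.94,2.68,36.10,46.80
17-18,male,17,18,height_cm,2322,169.78,6.22,157.00,181.99
17-18,female,17,18,height_cm,2894,157.66,5.45,147.00,169.00
17-18,male,17,18,weight_kg,2322,59.43,9.43,45.10,83.50
17-18,female,17,18,weight_kg,2897,51.97,7.00,41.00,68.50
17-18,male,17,18,bmi_kg_m2,2322,20.58,2.81,16.65,27.91
17-18,female,17,18,bmi_kg_m2,2894,20.90,2.54,16.79,26.88
17-18,male,17,18,heart_rate_bpm,2281,75.76,14.30,51.00,109.00
17-18,female,17,18,heart_rate_bpm,2864,83.88,13.33,62.00,115.00
17-18,male,17,18,creatinine_umol_L,1058,77.77,13.07,55.00,105.00
17-18,female,17,18,creatinine_umol_L,1031,60.43,12.12,40.80,84.00
17-18,male,17,18,albumin_g_L,1057,49.88,3.11,44.00,56.56
17-18,female,17,18,albumin_g_L,1030,48.89,3.07,43.30,55.50
17-18,male,17,18,hematocrit_pct,2030,46.84,2.90,40.90,52.20
17-18,female,17,18,hematocrit_pct,2548,41.73,2.64,36.20,46.70
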