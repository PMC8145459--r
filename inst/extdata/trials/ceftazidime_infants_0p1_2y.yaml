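name: ceftazidime_infants_0p1_2y
drug_name: ceftazidime
age_min_y: 0.1
age_max_y: 2
n_per_trial: 10
n_trials: 10
prop_female: 0.5
regimen: {route: iv_infusion, dose_mg_per_kg: 50, infusion_min: 30, interval_h: 24, n_doses: 1}
sampling_times_h: [0, 0.25, 0.5, 0.583, 0.75, 1, 1.25, 1.5, 2, 2.5, 3, 4, 5, 6, 8, 10, 12]
auc_horizon: inf
conc_scale: 1
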