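name: theophylline_children_6p6_12p25y
drug_name: theophylline
age_min_y: 6.6
age_max_y: 12.25
n_per_trial: 10
n_trials: 10
prop_female: 0.5
regimen: {route: iv_infusion, dose_mg_per_kg: 3.94, infusion_min: 30, interval_h: 24, n_doses: 1}
sampling_times_h: [0, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 16, 20, 24, 30, 36, 42, 48]
auc_horizon: inf
conc_scale: 1
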