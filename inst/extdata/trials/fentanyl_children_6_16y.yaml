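name: fentanyl_children_6_16y
drug_name: fentanyl
age_min_y: 6
age_max_y: 16
n_per_trial: 10
n_trials: 10
prop_female: 0.5
regimen: {route: iv_bolus, dose_mg_per_kg: 0.004, infusion_min: 0, interval_h: 24, n_doses: 1}
sampling_times_h: [0, 0.05, 0.1, 0.167, 0.25, 0.333, 0.5, 0.75, 1, 1.5, 2, 3, 4, 5, 6, 8, 10, 12]
auc_horizon: inf
conc_scale: 1000
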