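outcome,covariate,odds_ratio,or_unit,ci_lower,ci_upper,p_value,auc
seizure,max_pressure_kpa,1.005,per_kpa,1.003,1.006,1e-04,0.77
stimuli_response_30min,max_pressure_kpa,0.9978,per_kpa,0.9963,0.9992,0.01,0.79
tau_pathology,n_drops,1.099,per_drop,1.013,1.194,0.05,0.81
tau_pathology,max_pressure_kpa,1.004,per_kpa,1.003,1.006,1e-04,0.81
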