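item,value
n_users,18960
n_controls,56880
assessments_total,64128
cnn_low,37500
cnn_low_symptoms,8490
cnn_high,15083
cnn_failed,3055
telederm_upgrades,1277
telederm_downgrades,5098
tier1_fraction,0.883
high_risk_users,7041
low_risk_users,11919
history_users,885
cost_per_person_users,64.97
cost_per_person_controls,43.09
cost_delta,21.88
cost_delta_ci_low,17.90
cost_delta_ci_high,25.85
cost_premal_malig_users,31.01
cost_premal_malig_controls,20.88
cost_nevi_users,11.05
cost_nevi_controls,2.71
cost_unrelated_users,20.01
cost_unrelated_controls,18.47
cost_malignant_per_claim_users,613.36
cost_malignant_per_claim_controls,520.05
sens0,0.87
spec0,0.70
icer_reported,2567
icer_benign_reported,1843
icer_perfect_full,1119
icer_perfect_benign,488
icer_max,10839
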