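stratum,outcome,users_with,users_n,controls_with,controls_n
overall,premalignant,391,18960,896,56880
overall,malignant,773,18960,1785,56880
overall,nevus,850,18960,667,56880
overall,benign_tumor,267,18960,279,56880
overall,unrelated_dermatology,1001,18960,2800,56880
high_risk,premalignant,208,7041,399,21123
high_risk,malignant,442,7041,858,21123
high_risk,nevi_benign,695,7041,339,21123
high_risk,unrelated_dermatology,425,7041,1031,21123
low_risk,premalignant,183,11919,497,35757
low_risk,malignant,331,11919,927,35757
low_risk,nevi_benign,419,11919,602,35757
low_risk,unrelated_dermatology,576,11919,1769,35757
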