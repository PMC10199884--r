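.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".N", "person_id", "arm", "age", "cnn_result", "telederm_result",
  "assessment_index", "symptoms", "category", "intervention", "setting",
  "cost", "year", "stratum", "high", "risk", "any_high", "any_ok",
  "tier", "user_id", "control_id", "n", "fraction", "age_band",
  "comorb_capped", "n_comorbidities", "history_premalignancy", "ses",
  "region", "ok", "p_adjusted", "p_fisher", "p_zprop", "p_value",
  "d_detect", "d_benign", "icer_full", "icer_benign_only", "finite",
  "sens", "spec", ".arm", "outcome"))
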