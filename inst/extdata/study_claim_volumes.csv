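intervention,users_claims,controls_claims,users_n,controls_n
gp_biopsy_excision,1424,1913,18960,56880
gp_teledermatology,99,131,18960,56880
mohs,37,95,18960,56880
hospital_excision_benign,371,276,18960,56880
hospital_excision_premalignant,661,1129,18960,56880
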