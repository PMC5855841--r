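variable,type,sle_pos_mean,sle_pos_sd,sle_neg_mean,sle_neg_sd,sle_pos_count,sle_neg_count
age_years,numeric,13.7,11.6,16.2,9.6,,
ast_ui_ml,numeric,378,317.3,172,235.5,,
alt_ui_ml,numeric,277,220.6,216,327.1,,
pt_pct,numeric,95.4,13.1,95.9,24.0,,
aptt_s,numeric,33.3,4.6,31.5,6.0,,
f_ix_pct,numeric,49.5,14.9,75.2,25.0,,
f_xi_pct,numeric,35.9,15.1,59.3,35.5,,
at_iii_pct,numeric,43.0,14.1,51.2,26.8,,
protein_c_pct,numeric,38.6,17.2,83.4,129.9,,
protein_s_pct,numeric,52.9,22.6,63.5,17.5,,
mvrd,numeric,0.48,,0.41,,,
sex_male,categorical,,,,,3,21
vascular_personal_history,categorical,,,,,1,3
vascular_familial_history,categorical,,,,,1,2
febrile_seizures,categorical,,,,,2,4
epilepsy,categorical,,,,,2,6
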