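name,modality,scenario_label,sens_small,sens_medium,sens_large,sens_preclinical_early,sens_preclinical_late,specificity,positivity_mode
colonoscopy_high,colonoscopy,high,0.75,0.85,0.95,0.95,0.95,0.86,per_lesion
colonoscopy_low,colonoscopy,low,0.55,0.70,0.90,0.95,0.95,0.86,per_lesion
fit_per_person,fit,per_person,0.05,0.15,0.22,0.74,0.74,0.97,per_person
fit_per_lesion,fit,per_lesion,0.00,0.114,0.159,0.62565,0.886,0.97,per_lesion
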