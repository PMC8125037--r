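field,value
n_patients,125
n_male,80
n_female,45
mean_age_first_melanoma,57.3
mean_age_first_rcc,58.8
n_wes_subset,46
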