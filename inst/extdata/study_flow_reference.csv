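quantity,value
n_monitored,105
n_excluded_paroxysmal_af,5
n_poaf_long_term,31
n_poaf_missed_routine,12
n_ml_no_poaf,66
n_ml_poaf,28
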