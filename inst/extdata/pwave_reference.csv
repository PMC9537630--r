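feature,label,g0_mean,g0_sd,g1_mean,g1_sd,p_printed
pmax,Pmax (ms),167,31,184,37,0.018
pmin,Pmin (ms),105,22,104,19,0.872
pmean,Pmean (ms),133,23,141,25,0.162
pstd,Pstd (ms),15,7,19,11,0.031
pwd,PWd (ms),62,28,80,35,0.008
pptmean,Pptmean (ms),72,16,73,18,0.923
pptstd,Pptstd (ms),13,6,14,8,0.432
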