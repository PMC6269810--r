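system,H_r,H_d,S_r,S_d,Tr,Un
native,16.82,7.45,22.13,14.06,6.17,33.37
binary,13.46,5.22,20.14,14.01,6.03,41.14
ternary_alpha,12.09,4.66,18.28,12.84,5.86,46.27
ternary_beta,11.71,4.51,18.03,12.81,5.82,47.12
ternary_gamma,10.31,3.17,16.24,10.13,5.61,54.54
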