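population,n_lines,ms_genotype,ms_gxe,ms_error,n_env,n_rep
1,475,11517.27,4697.45,3638.18,3,2
2,72,13480.22,5013.41,3710.43,3,2
3,60,9300.02,3660.96,3290.85,3,2
4,68,19566.47,5731.30,3289.08,3,2
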