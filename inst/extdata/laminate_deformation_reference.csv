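n_cylinders,model_i_nm,model_ii_nm,model_iii_nm
1,0.786,0.478,0.316
2,0.182,0.110,0.072
3,0.054,0.033,0.022
4,0.017,0.011,0.008
5,0.009,0.006,0.005
6,0.006,0.004,0.003
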