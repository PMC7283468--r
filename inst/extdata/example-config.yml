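# Example run configuration: values are SI numbers or quantity strings.
F_am: 1 nN
lambda_ref: 30 min
R_c: 8 um
dt: 0.05
n_thr: 15
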