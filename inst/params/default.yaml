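# page4dyn 0.99.0
# seed: NA
# config_hash: 3bc79293
g_W: 0.008023807269973
k_H: 0.005349204846649
k_C: 0.254087230215827
delta_W: 0.004620981203733
delta_H: 0.001337301211662
delta_C: 0.010698409693298
delta_K: 0.026746024233245
delta_A: 0.026746024233245
g_A: 0.026746024233245
g_K: 0.026746024233245
H0: 0.1155
n_H: 4.0
A0: 0.0577
n_A: 4.0
beta_OE: 0.026746024233245

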