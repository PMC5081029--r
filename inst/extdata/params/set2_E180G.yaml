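# Set 2 with E180G changes: gamma x 0.75, K_BC x 1.10, delta x 1.15.
label: "Set 2 + E180G"
gamma: 28.20
K_BC: 2.1476
k_BC_ref: 7.0
f_ref: 0.132
delta: 0.5694
lam: 0.20
k_Ca_on: 0.1003
k_Ca_off: 0.471
RT: 2.577
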