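# Set 3 with E180G changes: gamma x 0.75, K_BC x 1.10, delta x 1.15.
label: "Set 4 (intact + E180G)"
gamma: 51.00
K_BC: 1.4259
k_BC_ref: 7.0
f_ref: 0.132
delta: 0.822
lam: 0.06
k_Ca_on: 6.0
k_Ca_off: 6.0
RT: 2.577
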