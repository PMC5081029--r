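# Set 2 with D175N changes: gamma x 0.60, K_BC x 0.85.
label: "Set 2 + D175N"
gamma: 22.60
K_BC: 1.6595
k_BC_ref: 7.0
f_ref: 0.132
delta: 0.4951
lam: 0.20
k_Ca_on: 0.1003
k_Ca_off: 0.471
RT: 2.577
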