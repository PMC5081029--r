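# Wild-type fit to reconstituted bovine myocardium (recombinant human Tm).
label: "Set 2 (reconstituted myocardium, WT)"
gamma: 37.64
K_BC: 1.9524
k_BC_ref: 7.0
f_ref: 0.132
delta: 0.4951
lam: 0.20
k_Ca_on: 0.1003
k_Ca_off: 0.471
RT: 2.577
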