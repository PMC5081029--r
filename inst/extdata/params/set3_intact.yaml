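# Wild-type fit to an intact rat trabecula twitch driven by its measured
# calcium transient.
label: "Set 3 (intact rat trabeculae, WT)"
gamma: 68.00
K_BC: 1.2963
k_BC_ref: 7.0
f_ref: 0.132
delta: 0.715
lam: 0.06
k_Ca_on: 6.0
k_Ca_off: 6.0
RT: 2.577
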