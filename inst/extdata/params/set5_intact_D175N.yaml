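# Set 3 with D175N changes as printed in the published parameter table
# (K_BC 1.212 is 0.935x the Set 3 value; the accompanying text states a
# 15% K_BC decrease, which scenario_D175N() applied to Set 3 gives instead).
label: "Set 5 (intact + D175N)"
gamma: 40.80
K_BC: 1.212
k_BC_ref: 7.0
f_ref: 0.132
delta: 0.715
lam: 0.06
k_Ca_on: 6.0
k_Ca_off: 6.0
RT: 2.577
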