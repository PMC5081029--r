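# Wild-type fit to skinned rat trabeculae steady-state force-pCa data.
label: "Set 1 (skinned rat trabeculae, WT)"
gamma: 68.00       # kJ/mol/rad^2
K_BC: 1.83
k_BC_ref: 0.898     # ms^-1
f_ref: 0.0058      # ms^-1
delta: 0.4754
lam: 0.0
k_Ca_on: 0.125     # uM^-1 ms^-1
k_Ca_off: 0.58     # ms^-1
RT: 2.577          # kJ/mol (310 K)
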