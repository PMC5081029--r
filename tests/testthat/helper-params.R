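# Shared fixtures: parameter sets built in code, small configs for fast runs.

set1 <- function() param_set("set1_skinned")
set2 <- function() param_set("set2_reconstituted")
set3 <- function() param_set("set3_intact")

# a soft, fast toy parameter set for structural tests
toy_params <- function(gamma = 10, lam = 0.2, K_BC = 1.5, delta = 0.5) {
  tm_params(gamma = gamma, K_BC = K_BC, k_BC_ref = 1, f_ref = 0.05,
            delta = delta, lam = lam, k_Ca_on = 0.1, k_Ca_off = 0.5)
}

quick_config <- function(n_runs = 30, duration = 1000, seed = 1, ...) {
  sim_config(n_runs = n_runs, duration = duration, seed = seed, ...)
}

# combined-SE z score for the difference of two estimates
zdiff <- function(a, sa, b, sb) (a - b) / sqrt(sa^2 + sb^2)
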