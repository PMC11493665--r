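# shared fixtures: parameter constructions used across test files

# closed trace-target construction: tiny conserved receptor pools, no
# turnover, no internalization -- the classical ternary-complex
# equilibrium regime
closed_trace_params <- function(base = table1_preset("consistent"),
                                scale = 1e-3) {
  q <- scale_params(base, "baseline_tcr", scale)
  q <- scale_params(q, "baseline_taa", scale)
  for (k in c("ksyn_tcr", "kdeg_tcr", "ksyn_taa", "kdeg_taa",
              "kint_tcr_dimer", "kint_taa_dimer", "kint_trimer"))
    q[[k]] <- 0
  q
}

# turnover balanced, internalization off: detailed-balance regime where
# free receptors sit at baseline and complexes obey mass-action ratios
no_internalization_params <- function(base = table1_preset("consistent")) {
  for (k in c("kint_tcr_dimer", "kint_taa_dimer", "kint_trimer"))
    base[[k]] <- 0
  base
}

# multiply every independent parameter by the matching factor, re-deriving
# koff (dialect-preserving) and ksyn via scale_params()
apply_fold_factors <- function(base, factors) {
  q <- base
  for (k in names(factors)) q <- scale_params(q, k, factors[[k]])
  q
}

independent_param_names <- function() {
  c("kon_tcr", "kon_taa", "kd_tcr", "kd_taa", "kdeg_tcr", "kdeg_taa",
    "kint_tcr_dimer", "kint_taa_dimer", "kint_trimer",
    "baseline_tcr", "baseline_taa")
}

# totals that are conserved when turnover and internalization are off
pool_totals <- function(states) {
  cbind(tce = rowSums(states[, c("tce", "tce_tcr", "tce_taa", "trimer")]),
        tcr = rowSums(states[, c("tcr", "tce_tcr", "trimer")]),
        taa = rowSums(states[, c("taa", "tce_taa", "trimer")]))
}
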