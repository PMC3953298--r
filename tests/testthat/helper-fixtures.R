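# Shared fixtures: default parameters and a deterministic generator of
# random valid states for property-style tests.

default_params <- gnrh_parameters()

random_states <- function(n, params = default_params, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    erk <- stats::runif(5)
    erk <- erk / sum(erk) * params[["ERK_tot"]]
    c(HR = stats::runif(1, 0, params[["R0"]]),
      GQ = stats::runif(1, 0, params[["GQ_tot"]]),
      E = stats::runif(1, 0, 2),
      E_c = erk[1], pE_c = erk[2], ppE_c = erk[3],
      E_n = erk[4] * params[["C_cn"]], ppE_n = erk[5] * params[["C_cn"]],
      TF1 = stats::runif(1, 0, 1.5), TF1DT = stats::runif(1, 0, 0.6))
  })
}
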