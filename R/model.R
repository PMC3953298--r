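# Model core: algebraic MEK activation, the distributive dual
# (de)phosphorylation fluxes, and the ten-species right-hand side.
#
# States (uM, per compartment):
#   HR    hormone-bound receptor
#   GQ    free G protein
#   E     active effector
#   E_c   unphosphorylated cytosolic ERK
#   pE_c  mono-phosphorylated cytosolic ERK
#   ppE_c dual-phosphorylated (active) cytosolic ERK
#   E_n   unphosphorylated nuclear ERK
#   ppE_n dual-phosphorylated nuclear ERK
#   TF1   active transcription factor
#   TF1DT TF1-dependent transcript
#
# This file is the readable reference implementation; simulate() integrates
# an identical right-hand side compiled in src/model.c.

.state_names <- c("HR", "GQ", "E", "E_c", "pE_c", "ppE_c",
                  "E_n", "ppE_n", "TF1", "TF1DT")

#' Active MEK as an algebraic function of the effector
#'
#' MEK activation is treated as fast relative to the rest of the cascade and
#' replaced by its quasi-steady state,
#' \deqn{ppMEK = MEK_{tot}\frac{k_{MEK,basal} + k_{mek} E}{k_{MEK,basal} +
#'   k_{mek}(K_{MM,MEK} + E)},}
#' which at the default basal rate of 0 reduces to the Michaelis-Menten form
#' \eqn{MEK_{tot} E / (K_{MM,MEK} + E)}.
#'
#' @param E active effector concentration, uM (>= 0).
#' @param params a [gnrh_parameters()] object.
#' @return active (dual-phosphorylated) MEK, uM, in `[0, MEK_tot]`.
#' @examples
#' mek_active(0.05, gnrh_parameters())  # half-saturation: MEK_tot/2 = 0.3
#' @export
mek_active <- function(E, params) {
  if (any(E < 0)) stop("E must be non-negative")
  kb <- params[["k_MEK_basal"]]
  km <- params[["k_mek"]]
  denom <- kb + km * (params[["K_MM_MEK"]] + E)
  ifelse(denom > 0, params[["MEK_tot"]] * (kb + km * E) / denom, 0)
}

#' ERK (de)phosphorylation fluxes
#'
#' The five fluxes of the distributive two-site scheme: v1/v2 are the two
#' MEK-catalysed phosphorylation steps (cytoplasm only), v3/v4 the cytosolic
#' phosphatase steps with competitive inhibition among ERK forms, and v5 the
#' one-step nuclear dephosphorylation of ppERK.
#'
#' @param state named numeric state vector (see [resting_state()] for the
#'   layout).
#' @param ppMEK active MEK, uM.
#' @param params a [gnrh_parameters()] object.
#' @param mek_inhibited if `TRUE`, the MEK-catalysed fluxes v1 and v2 are
#'   forced to zero (pharmacological MEK blockade).
#' @return named numeric vector `c(v1, v2, v3, v4, v5)`, uM/min.
#' @export
phospho_fluxes <- function(state, ppMEK, params, mek_inhibited = FALSE) {
  E_c <- state[["E_c"]]; pE_c <- state[["pE_c"]]; ppE_c <- state[["ppE_c"]]
  ppE_n <- state[["ppE_n"]]
  km1 <- params[["km_1"]]; km2 <- params[["km_2"]]; km3 <- params[["km_3"]]
  km4 <- params[["km_4"]]; km5 <- params[["km_5"]]
  v1 <- params[["kcat_1"]] * ppMEK * E_c / (km1 * (1 + pE_c / km2) + E_c)
  v2 <- params[["kcat_2"]] * ppMEK * pE_c / (km2 * (1 + E_c / km1) + pE_c)
  v3 <- params[["kcat_3"]] * params[["MKP_c"]] * ppE_c /
    (km3 * (1 + pE_c / km4 + E_c / km5) + ppE_c)
  v4 <- params[["kcat_4"]] * params[["MKP_c"]] * pE_c /
    (km4 * (1 + ppE_c / km3 + E_c / km5) + pE_c)
  v5 <- params[["kcat_5"]] * params[["MKP_n"]] * ppE_n /
    (params[["kd_ppEn"]] + ppE_n)
  if (mek_inhibited) {
    v1 <- 0
    v2 <- 0
  }
  c(v1 = v1, v2 = v2, v3 = v3, v4 = v4, v5 = v5)
}

#' Right-hand side of the model ODE system
#'
#' Time derivatives of the ten states under a given protocol. Receptor
#' occupancy follows mass-action ligand binding; occupied receptor consumes
#' free G protein to produce the effector, which activates MEK algebraically
#' ([mek_active()]); ERK is phosphorylated distributively in the cytoplasm,
#' dephosphorylated in both compartments, and shuttles between them; active
#' cytosolic ERK feeds back on the effector; nuclear ppERK drives TF1 and
#' TF1 drives its transcript, both through saturating kinetics. Transport
#' terms carry the volume-ratio factors so that ERK amount is conserved.
#'
#' @param t time, min.
#' @param state named numeric state vector.
#' @param params a [gnrh_parameters()] object.
#' @param protocol a [gnrh_protocol()]; supplies the GnRH input and the MEK
#'   inhibition window.
#' @return named numeric vector of derivatives, uM/min.
#' @export
gnrh_rhs <- function(t, state, params, protocol) {
  if (any(!is.finite(state))) stop("non-finite state component")
  G <- gnrh_input(t, protocol)
  mek_inh <- t >= .event_time(protocol, "mek_inhibition")
  .rhs_core(state, params, G, mek_inh)
}

.rhs_core <- function(state, params, G, mek_inhibited) {
  HR <- state[["HR"]]; GQ <- state[["GQ"]]; E <- state[["E"]]
  E_c <- state[["E_c"]]; ppE_c <- state[["ppE_c"]]
  E_n <- state[["E_n"]]; ppE_n <- state[["ppE_n"]]
  TF1 <- state[["TF1"]]; TF1DT <- state[["TF1DT"]]
  C_cn <- params[["C_cn"]]

  ppMEK <- mek_active(E, params)
  v <- phospho_fluxes(state, ppMEK, params, mek_inhibited)
  fb <- if (identical(attr(params, "feedback"), "nuclear")) ppE_n else ppE_c

  c(HR = params[["k1"]] * G * (params[["R0"]] - HR) - params[["k_minus1"]] * HR,
    GQ = -params[["k2"]] * HR * GQ +
      params[["k_minus2"]] * (params[["GQ_tot"]] - GQ),
    E = params[["k2"]] * HR * GQ - params[["k_minus3"]] * E -
      params[["k3"]] * fb * E,
    E_c = -v[["v1"]] + v[["v4"]] - params[["k_imp"]] * E_c +
      params[["k_exp"]] / C_cn * E_n,
    pE_c = v[["v1"]] - v[["v2"]] + v[["v3"]] - v[["v4"]],
    ppE_c = v[["v2"]] - v[["v3"]] - params[["k_imp_act"]] * ppE_c +
      params[["k_exp_act"]] / C_cn * ppE_n,
    E_n = C_cn * params[["k_imp"]] * E_c - params[["k_exp"]] * E_n + v[["v5"]],
    ppE_n = C_cn * params[["k_imp_act"]] * ppE_c -
      params[["k_exp_act"]] * ppE_n - v[["v5"]],
    TF1 = params[["k_TF1"]] * ppE_n / (params[["K_MM_TF1"]] + ppE_n) -
      params[["d_TF1"]] * TF1,
    TF1DT = params[["k_TF1DT"]] * TF1 / (params[["K_MM_TF1DT"]] + TF1) -
      params[["d_TF1DT"]] * TF1DT)
}

#' Pre-stimulus resting state
#'
#' The unstimulated fixed point: no occupied receptor, full free G-protein
#' pool, no active effector and no phosphorylated ERK; unphosphorylated ERK
#' is partitioned between cytoplasm and nucleus by the import/export balance
#' `E_n / E_c = C_cn * k_imp / k_exp` subject to total-ERK conservation
#' `E_c + E_n / C_cn = ERK_tot`.
#'
#' @param params a [gnrh_parameters()] object.
#' @return named numeric state vector at which the right-hand side vanishes
#'   (checked to 1e-9 componentwise).
#' @examples
#' s <- resting_state(gnrh_parameters())
#' s[["E_n"]] / s[["E_c"]]   # 0.8 at default shuttling rates
#' @export
resting_state <- function(params) {
  r <- params[["k_imp"]] / params[["k_exp"]]
  E_c <- params[["ERK_tot"]] / (1 + r)
  E_n <- params[["C_cn"]] * r * E_c
  s <- c(HR = 0, GQ = params[["GQ_tot"]], E = 0,
         E_c = E_c, pE_c = 0, ppE_c = 0, E_n = E_n, ppE_n = 0,
         TF1 = 0, TF1DT = 0)
  d <- .rhs_core(s, params, G = 0, mek_inhibited = FALSE)
  if (max(abs(d)) >= 1e-9)
    stop("resting state is not a fixed point (max |rhs| = ", max(abs(d)), ")")
  s
}

#' Conservation and positivity diagnostics for a state
#'
#' @param state named numeric state vector.
#' @param params a [gnrh_parameters()] object.
#' @return list with `erk_residual`, the deviation of
#'   `(E_c + pE_c + ppE_c) + (E_n + ppE_n)/C_cn` from `ERK_tot`, and
#'   `violations`, a character vector naming any negative components or
#'   totals exceeding their bounds (`HR > R0`, `GQ > GQ_tot`).
#' @export
conservation_residuals <- function(state, params) {
  cyto <- state[["E_c"]] + state[["pE_c"]] + state[["ppE_c"]]
  nuc <- (state[["E_n"]] + state[["ppE_n"]]) / params[["C_cn"]]
  residual <- cyto + nuc - params[["ERK_tot"]]
  viol <- character()
  neg <- names(state)[state < 0]
  if (length(neg)) viol <- c(viol, paste0(neg, " < 0"))
  if (state[["HR"]] > params[["R0"]] + 1e-12) viol <- c(viol, "HR > R0")
  if (state[["GQ"]] > params[["GQ_tot"]] + 1e-12) viol <- c(viol, "GQ > GQ_tot")
  list(erk_residual = unname(residual), violations = viol)
}
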