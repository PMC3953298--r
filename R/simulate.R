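# Trajectory integration. The square-wave input and the interventions make
# the right-hand side discontinuous at known times, so integration proceeds
# piecewise: the protocol is split into segments on which the GnRH input and
# the MEK-inhibition flag are constant, and the stiff-capable adaptive solver
# is restarted at every segment boundary. Within a segment the input is a
# constant, which is what the compiled right-hand side assumes.

.RTOL <- 1e-8
.ATOL <- 1e-10

# Split [0, horizon] at every pulse edge and event time. Returns a data frame
# with one row per segment: [t0, t1), the constant GnRH input on it, and
# whether MEK is inhibited.
.segment_plan <- function(protocol) {
  h <- protocol$horizon
  wash <- .event_time(protocol, "washout")
  mek <- .event_time(protocol, "mek_inhibition")
  edges <- c(0, h)
  if (protocol$width < protocol$period) {
    starts <- seq(0, h, by = protocol$period)
    edges <- c(edges, starts, starts + protocol$width)
  }
  if (is.finite(wash)) edges <- c(edges, wash)
  if (is.finite(mek)) edges <- c(edges, mek)
  edges <- sort(unique(edges[edges >= 0 & edges <= h]))
  t0 <- edges[-length(edges)]
  t1 <- edges[-1]
  # classify each segment at its midpoint: edge times themselves are subject
  # to floating-point wobble in the modulo (e.g. 60.9 %% 60 < 0.9)
  data.frame(t0 = t0, t1 = t1,
             gnrh = gnrh_input((t0 + t1) / 2, protocol),
             mek = t0 >= mek)
}

# Resting initial condition from a bare parameter vector (positional; layout
# of .param_names). Used on the fitting hot path.
.resting_from_vector <- function(pv) {
  r <- pv[12] / pv[10]              # k_imp / k_exp
  E_c <- pv[16] / (1 + r)           # ERK_tot
  E_n <- pv[31] * r * E_c           # C_cn
  c(HR = 0, GQ = pv[8], E = 0, E_c = E_c, pE_c = 0, ppE_c = 0,
    E_n = E_n, ppE_n = 0, TF1 = 0, TF1DT = 0)
}

# Core integrator: piecewise lsoda over a segment plan, compiled rhs.
# `times` are the requested output times; segment boundaries are added
# internally and the result is returned exactly at `times` (a matrix with a
# time column and the ten states).
.simulate_core <- function(pv, fb_nuclear, plan, times, y0 = NULL) {
  if (is.null(y0)) y0 <- .resting_from_vector(pv)
  all_times <- sort(unique(c(times, plan$t0, plan$t1)))
  out <- matrix(NA_real_, nrow = length(all_times), ncol = 11,
                dimnames = list(NULL, c("time", .state_names)))
  y <- y0
  row <- 1
  for (i in seq_len(nrow(plan))) {
    t0 <- plan$t0[i]; t1 <- plan$t1[i]
    tt <- all_times[all_times >= t0 & all_times <= t1]
    parms <- c(pv, plan$gnrh[i], as.numeric(plan$mek[i]), fb_nuclear)
    seg <- deSolve::lsoda(y = y, times = tt, func = "gnrh_derivs",
                          parms = parms, dllname = "gnrhpulse",
                          initfunc = "gnrh_init",
                          rtol = .RTOL, atol = .ATOL)
    if (nrow(seg) < length(tt) || anyNA(seg))
      stop(sprintf("ODE solver failed on segment [%g, %g] min", t0, t1))
    keep <- if (i == 1) seq_len(nrow(seg)) else seq.int(2, nrow(seg))
    out[seq.int(row, row + length(keep) - 1), ] <- seg[keep, , drop = FALSE]
    row <- row + length(keep)
    y <- seg[nrow(seg), -1]
  }
  out[all_times %in% times, , drop = FALSE]
}

#' Derived observables of a state
#'
#' The measurement-facing quantities: whole-cell ppERK as the volume-weighted
#' mean of the compartmental ppERK concentrations,
#' `(C_cn * ppE_c + ppE_n) / (C_cn + 1)`; the nuclear:cytoplasmic ratio of
#' total ERK, `(E_n + ppE_n) / (E_c + pE_c + ppE_c)` (the ERK2-GFP imaging
#' readout); and active MEK via [mek_active()]. Small negative solver
#' undershoots are clipped to zero here (never in the propagated state).
#'
#' @param state named numeric state vector.
#' @param params a [gnrh_parameters()] object.
#' @return named numeric vector `c(wholecell_ppERK, NC_ERK, ppMEK)`, with the
#'   ratio dimensionless and the others in uM.
#' @export
observables <- function(state, params) {
  s <- pmax(state, 0)
  cyto <- s[["E_c"]] + s[["pE_c"]] + s[["ppE_c"]]
  if (cyto <= 0) stop("N:C ratio undefined: cytosolic ERK total is zero")
  C_cn <- params[["C_cn"]]
  c(wholecell_ppERK = (C_cn * s[["ppE_c"]] + s[["ppE_n"]]) / (C_cn + 1),
    NC_ERK = (s[["E_n"]] + s[["ppE_n"]]) / cyto,
    ppMEK = unname(mek_active(s[["E"]], params)))
}

#' Simulate the model over a protocol
#'
#' Integrates the ten-species system from the resting state (or a supplied
#' initial condition) over `[0, horizon]`, restarting the adaptive solver at
#' every pulse edge and intervention time. The output grid is the requested
#' regular grid plus every segment boundary, so pulse edges are always
#' represented exactly. Fully deterministic.
#'
#' @param params a [gnrh_parameters()] object.
#' @param protocol a [gnrh_protocol()].
#' @param output_step output grid spacing, min.
#' @param init optional initial state (named, in the layout of
#'   [resting_state()]); defaults to the resting state.
#' @return a `gnrh_trajectory`: a data frame with columns `time`, the ten
#'   states, and the derived columns `gnrh`, `ppmek`, `pperk_wholecell`,
#'   `nc_erk`; the generating `params` and `protocol` are attached as
#'   attributes.
#' @examples
#' p <- gnrh_parameters()
#' tr <- simulate_protocol(p, single_pulse(1e-7, 1, 30), output_step = 0.5)
#' tr$time[which.max(tr$pperk_wholecell)]  # ppERK peaks well after the pulse
#' @export
simulate_protocol <- function(params, protocol, output_step = 0.5,
                              init = NULL) {
  stopifnot(inherits(params, "gnrh_params"),
            inherits(protocol, "gnrh_protocol"),
            is.numeric(output_step), output_step > 0)
  plan <- .segment_plan(protocol)
  times <- sort(unique(c(seq(0, protocol$horizon, by = output_step),
                         protocol$horizon, plan$t0, plan$t1)))
  fb <- as.numeric(identical(attr(params, "feedback"), "nuclear"))
  out <- .simulate_core(as.numeric(params), fb, plan, times, y0 = init)

  states <- out[, .state_names, drop = FALSE]
  if (min(states) < -1e-8)
    stop("solver undershoot beyond -1e-8 (min state ", min(states), ")")
  sc <- pmax(states, 0)
  cyto <- sc[, "E_c"] + sc[, "pE_c"] + sc[, "ppE_c"]
  if (any(cyto <= 0)) stop("N:C ratio undefined: cytosolic ERK total is zero")
  C_cn <- params[["C_cn"]]
  traj <- data.frame(time = out[, "time"], states,
                     gnrh = gnrh_input(out[, "time"], protocol),
                     ppmek = mek_active(sc[, "E"], params),
                     pperk_wholecell =
                       (C_cn * sc[, "ppE_c"] + sc[, "ppE_n"]) / (C_cn + 1),
                     nc_erk = (sc[, "E_n"] + sc[, "ppE_n"]) / cyto)
  structure(traj, class = c("gnrh_trajectory", "data.frame"),
            params = params, protocol = protocol)
}

# Plain-R right-hand side on a bare numeric vector, positional layout; used
# by the fixed-step oracle where the named reference gnrh_rhs() would be too
# slow. Tested for exact agreement with gnrh_rhs().
.rhs_fast <- function(y, pv, G, mek_inh, fb_nuclear) {
  denom <- pv[15] + pv[13] * (pv[14] + y[3])
  ppMEK <- if (denom > 0) pv[17] * (pv[15] + pv[13] * y[3]) / denom else 0
  v1 <- pv[18] * ppMEK * y[4] / (pv[23] * (1 + y[5] / pv[24]) + y[4])
  v2 <- pv[19] * ppMEK * y[5] / (pv[24] * (1 + y[4] / pv[23]) + y[5])
  v3 <- pv[20] * pv[30] * y[6] /
    (pv[25] * (1 + y[5] / pv[26] + y[4] / pv[27]) + y[6])
  v4 <- pv[21] * pv[30] * y[5] /
    (pv[26] * (1 + y[6] / pv[25] + y[4] / pv[27]) + y[5])
  v5 <- pv[22] * pv[29] * y[8] / (pv[28] + y[8])
  if (mek_inh) { v1 <- 0; v2 <- 0 }
  fb <- if (fb_nuclear) y[8] else y[6]
  c(pv[2] * G * (pv[1] - y[1]) - pv[3] * y[1],
    -pv[4] * y[1] * y[2] + pv[5] * (pv[8] - y[2]),
    pv[4] * y[1] * y[2] - pv[7] * y[3] - pv[6] * fb * y[3],
    -v1 + v4 - pv[12] * y[4] + pv[10] / pv[31] * y[7],
    v1 - v2 + v3 - v4,
    v2 - v3 - pv[11] * y[6] + pv[9] / pv[31] * y[8],
    pv[31] * pv[12] * y[4] - pv[10] * y[7] + v5,
    pv[31] * pv[11] * y[6] - pv[9] * y[8] - v5,
    pv[33] * y[8] / (pv[34] + y[8]) - pv[32] * y[9],
    pv[36] * y[9] / (pv[37] + y[9]) - pv[35] * y[10])
}

#' Fixed-step reference integration
#'
#' Integrates the same right-hand side with a classical fixed-step
#' fourth-order Runge-Kutta scheme (restarted at the same segment
#' boundaries). This is a verification oracle for [simulate_protocol()]:
#' slower, independent of the adaptive solver, intended for tests.
#'
#' @param params a [gnrh_parameters()] object.
#' @param protocol a [gnrh_protocol()].
#' @param step fixed integration step, min (small; 0.001 recommended).
#' @param output_step output grid spacing, min.
#' @return a data frame `time` plus the ten states.
#' @export
oracle_simulate <- function(params, protocol, step = 0.001, output_step = 1) {
  stopifnot(step > 0, output_step > 0)
  pv <- as.numeric(params)
  fb_nuclear <- identical(attr(params, "feedback"), "nuclear")
  plan <- .segment_plan(protocol)
  times <- sort(unique(c(seq(0, protocol$horizon, by = output_step),
                         protocol$horizon, plan$t0, plan$t1)))
  out <- matrix(NA_real_, nrow = length(times), ncol = 11,
                dimnames = list(NULL, c("time", .state_names)))
  y <- unname(resting_state(params))
  row <- 1
  for (i in seq_len(nrow(plan))) {
    t0 <- plan$t0[i]; t1 <- plan$t1[i]
    G <- plan$gnrh[i]; mek <- plan$mek[i]
    record <- times[times >= t0 & times <= t1]
    if (i > 1) record <- record[record > t0]
    # step through [t0, t1], landing exactly on every recording time
    targets <- sort(unique(c(record, t1)))
    t <- t0
    for (tg in targets) {
      n <- max(1L, ceiling((tg - t) / step - 1e-9))
      h <- (tg - t) / n
      for (k in seq_len(n)) {
        k1 <- .rhs_fast(y, pv, G, mek, fb_nuclear)
        k2 <- .rhs_fast(y + h / 2 * k1, pv, G, mek, fb_nuclear)
        k3 <- .rhs_fast(y + h / 2 * k2, pv, G, mek, fb_nuclear)
        k4 <- .rhs_fast(y + h * k3, pv, G, mek, fb_nuclear)
        y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      t <- tg
      if (tg %in% record) {
        out[row, ] <- c(tg, y)
        row <- row + 1
      }
    }
  }
  as.data.frame(out)
}
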