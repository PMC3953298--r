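# Integrated-response analyses: area under the curve above the pre-stimulus
# baseline for each measure along the cascade, as a function of pulse
# frequency, width, amplitude and receptor number, plus the post-pulse ppERK
# fraction and the washout-vs-MEK-inhibitor termination ratio.

.measures <- c("GnRH", "HR", "E", "ppERK", "NC_ERK", "TF1", "TF1DT")

.measure_column <- c(GnRH = "gnrh", HR = "HR", E = "E",
                     ppERK = "pperk_wholecell", NC_ERK = "nc_erk",
                     TF1 = "TF1", TF1DT = "TF1DT")

#' Area under a curve above a baseline
#'
#' Trapezoidal integral of `value - baseline`. The deviation is signed (not
#' clipped at zero): model trajectories do not undershoot their pre-stimulus
#' baseline, and clipping would mask bugs if they ever did.
#'
#' @param time strictly increasing time points, min.
#' @param value measure values at `time`.
#' @param baseline scalar baseline subtracted before integration.
#' @return integral in `units(value) * min`.
#' @examples
#' auc(c(0, 1, 2), c(0, 2, 0))   # triangle, area 2
#' @export
auc <- function(time, value, baseline = 0) {
  stopifnot(length(time) >= 2, length(value) == length(time))
  if (is.unsorted(time, strictly = TRUE))
    stop("times must be strictly increasing")
  dv <- value - baseline
  n <- length(dv)
  sum(diff(time) * (dv[-n] + dv[-1]) / 2)
}

# Pre-stimulus baseline of each measure (resting values; only the N:C ratio
# is nonzero at rest).
.measure_baselines <- function(params) {
  rest <- resting_state(params)
  obs <- observables(rest, params)
  c(GnRH = 0, HR = 0, E = 0, ppERK = 0,
    NC_ERK = unname(obs[["NC_ERK"]]), TF1 = 0, TF1DT = 0)
}

# Exact integral of the square-wave input over [0, horizon] (the input is
# known analytically; sampling a discontinuous signal onto the output grid
# would bias its AUC).
.gnrh_auc <- function(protocol) {
  starts <- seq(0, protocol$horizon, by = protocol$period)
  stop_at <- min(.event_time(protocol, "washout"), protocol$horizon)
  ends <- pmin(starts + protocol$width, stop_at)
  starts <- pmin(starts, stop_at)
  sum(pmax(ends - starts, 0)) * protocol$p
}

# One protocol -> integrated response of every measure (long format rows).
.response_rows <- function(params, protocol, output_step) {
  traj <- simulate_protocol(params, protocol, output_step = output_step)
  base <- .measure_baselines(params)
  vapply(.measures, function(m) {
    if (m == "GnRH") return(.gnrh_auc(protocol))
    auc(traj$time, traj[[.measure_column[[m]]]], base[[m]])
  }, numeric(1))
}

.response_table <- function(params, grid, amplitude_molar, horizon,
                            output_step) {
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    prot <- pulse_train(amplitude_molar, width = grid$width[i],
                        interval = grid$interval[i], horizon = horizon)
    a <- .response_rows(params, prot, output_step)
    data.frame(measure = .measures,
               width_min = grid$width[i],
               interval_min = grid$interval[i],
               amplitude_uM = amplitude_molar * MOLAR_TO_UM,
               R0_uM = params[["R0"]],
               frequency_per_h = 60 / grid$interval[i],
               auc = unname(a))
  })
  tab <- do.call(rbind, rows)
  # normalize each measure to its value at the maximal simulated frequency
  ref <- tab[tab$interval_min == min(tab$interval_min), ]
  ref_auc <- stats::setNames(ref$auc, ref$measure)
  tab$auc_normalized <- tab$auc / ref_auc[tab$measure]
  class(tab) <- c("gnrh_response_table", "data.frame")
  tab
}

#' Integrated responses as a function of pulse frequency
#'
#' Simulates a pulse train for each interval at fixed width and amplitude and
#' integrates every measure along the cascade above its resting baseline.
#' Including `interval = width` in `intervals` adds the constant-stimulation
#' (maximal-frequency) reference row; `auc_normalized` divides each measure
#' by its value at the maximal simulated frequency.
#'
#' @param params a [gnrh_parameters()] object.
#' @param width pulse width, min.
#' @param intervals pulse intervals, min (each >= `width`).
#' @param amplitude_molar pulse amplitude, mol/L.
#' @param horizon simulated time, min.
#' @param output_step trajectory output step used for the integrals, min.
#' @return a `gnrh_response_table` data frame with columns `measure`,
#'   `width_min`, `interval_min`, `amplitude_uM`, `R0_uM`,
#'   `frequency_per_h`, `auc`, `auc_normalized`.
#' @export
frequency_response <- function(params, width = 1,
                               intervals = c(width, 15, 30, 45, 60, 90,
                                             120, 240),
                               amplitude_molar = 1e-7, horizon = 480,
                               output_step = 0.5) {
  stopifnot(all(intervals >= width))
  .response_table(params,
                  grid = data.frame(width = width, interval = intervals),
                  amplitude_molar = amplitude_molar, horizon = horizon,
                  output_step = output_step)
}

#' Integrated responses as a function of pulse width
#'
#' Companion to [frequency_response()]: the interval is fixed and the pulse
#' width varied. A row with `width = interval` is the same constant-stimulation
#' reference row as in the frequency analysis.
#'
#' @inheritParams frequency_response
#' @param widths pulse widths, min (each <= `interval`).
#' @param interval fixed pulse interval, min.
#' @return a `gnrh_response_table` data frame; see [frequency_response()].
#' @export
width_response <- function(params, widths = c(1, 2.5, 5, 10, 20, 30, 60),
                           interval = 60, amplitude_molar = 1e-7,
                           horizon = 480, output_step = 0.5) {
  stopifnot(all(widths <= interval))
  tab <- .response_table(params,
                         grid = data.frame(width = widths,
                                           interval = interval),
                         amplitude_molar = amplitude_molar,
                         horizon = horizon, output_step = output_step)
  # normalization reference for the width axis: the constant-stimulation row
  # if present, else the widest pulse
  ref <- tab[tab$width_min == max(tab$width_min), ]
  ref_auc <- stats::setNames(ref$auc, ref$measure)
  tab$auc_normalized <- tab$auc / ref_auc[tab$measure]
  tab
}

#' Integrated receptor occupancy over a protocol
#'
#' @param params a [gnrh_parameters()] object.
#' @param protocol a [gnrh_protocol()].
#' @param output_step trajectory output step, min.
#' @return integral of bound receptor HR over time, uM min.
#' @export
integrated_hr <- function(params, protocol, output_step = 0.5) {
  traj <- simulate_protocol(params, protocol, output_step = output_step)
  auc(traj$time, traj$HR, 0)
}

#' Fraction of the ppERK response occurring after the pulse
#'
#' Simulates a single washout-terminated pulse and returns the share of the
#' integrated whole-cell ppERK response that falls after the pulse end.
#'
#' @param params a [gnrh_parameters()] object.
#' @param width pulse width, min (< `horizon`).
#' @param amplitude_molar pulse amplitude, mol/L.
#' @param horizon observation window, min.
#' @param output_step trajectory output step, min.
#' @return fraction in `[0, 1]`.
#' @examples
#' \donttest{
#' post_pulse_fraction(gnrh_parameters(), width = 1, horizon = 30)  # >= 0.9
#' }
#' @export
post_pulse_fraction <- function(params, width = 1, amplitude_molar = 1e-7,
                                horizon = 30, output_step = 0.1) {
  prot <- single_pulse(amplitude_molar, width, horizon,
                       termination = "washout")
  traj <- simulate_protocol(params, prot, output_step = output_step)
  total <- auc(traj$time, traj$pperk_wholecell, 0)
  if (total <= 0) stop("total ppERK response is zero")
  post <- traj$time >= width
  auc(traj$time[post], traj$pperk_wholecell[post], 0) / total
}

#' Frequency-axis vs width-axis sensitivity of an integrated measure
#'
#' At a base protocol, the integrated receptor occupancy (HR) can be varied
#' either by changing pulse frequency or by changing pulse width. This
#' returns the ratio of the numerical gradients
#' d(integrated measure)/d(integrated HR) along the two axes (central
#' differences, +/-10% perturbation). A ratio near 1 means the measure only
#' tracks integrated occupancy; a ratio above 1 means the measure is more
#' sensitive to pulse frequency than to pulse width.
#'
#' @param params a [gnrh_parameters()] object.
#' @param measure one of `r paste0('"', .measures, '"', collapse = ", ")`.
#' @param base_width,base_interval base protocol, min.
#' @param amplitude_molar pulse amplitude, mol/L.
#' @param horizon simulated time, min.
#' @param rel_step relative perturbation for the central differences.
#' @param output_step trajectory output step, min.
#' @return the gradient ratio (frequency-axis / width-axis).
#' @export
sensitivity_gradient_ratio <- function(params, measure = "ppERK",
                                       base_width = 1, base_interval = 60,
                                       amplitude_molar = 1e-7, horizon = 480,
                                       rel_step = 0.1, output_step = 0.5) {
  measure <- match.arg(measure, .measures)
  point <- function(width, interval) {
    a <- .response_rows(params,
                        pulse_train(amplitude_molar, width, interval,
                                    horizon),
                        output_step)
    c(m = unname(a[[measure]]), hr = unname(a[["HR"]]))
  }
  # frequency axis: perturb the interval, width fixed
  f_hi <- point(base_width, base_interval * (1 - rel_step))  # higher frequency
  f_lo <- point(base_width, base_interval * (1 + rel_step))
  grad_f <- (f_hi[["m"]] - f_lo[["m"]]) / (f_hi[["hr"]] - f_lo[["hr"]])
  # width axis: perturb the width, interval fixed
  w_hi <- point(base_width * (1 + rel_step), base_interval)
  w_lo <- point(base_width * (1 - rel_step), base_interval)
  dhr_w <- w_hi[["hr"]] - w_lo[["hr"]]
  if (abs(dhr_w) < .Machine$double.eps^0.5)
    stop("degenerate width axis: integrated HR does not respond to width")
  grad_w <- (w_hi[["m"]] - w_lo[["m"]]) / dhr_w
  if (abs(grad_w) < .Machine$double.eps^0.5)
    stop("degenerate (zero) width gradient for measure ", measure)
  unname(grad_f / grad_w)
}

#' Transcript ratio for inhibitor- vs washout-terminated pulses
#'
#' For each pulse width, a single GnRH pulse is terminated either by washout
#' or by MEK inhibition and the TF1-dependent transcript is read out at
#' `total_time`. The ratio (inhibitor / washout) quantifies how much of the
#' transcriptional output depends on ERK activity occurring after the pulse:
#' it is below 1 for short pulses and approaches 1 as the pulse fills the
#' incubation.
#'
#' @param params a [gnrh_parameters()] object.
#' @param widths pulse widths, min (each <= `total_time`).
#' @param amplitude_molar pulse amplitude, mol/L.
#' @param total_time incubation time at which the transcript is read, min.
#' @param output_step trajectory output step, min.
#' @return data frame with columns `width_min`, `tf1dt_mek`, `tf1dt_wash`,
#'   `ratio`.
#' @export
termination_ratio <- function(params, widths = c(1, 5, 15, 30, 60),
                              amplitude_molar = 1e-7, total_time = 360,
                              output_step = 0.5) {
  stopifnot(all(widths <= total_time), all(widths > 0))
  endpoint <- function(width, termination) {
    traj <- simulate_protocol(params,
                              single_pulse(amplitude_molar, width,
                                           total_time, termination),
                              output_step = output_step)
    traj$TF1DT[nrow(traj)]
  }
  rows <- lapply(widths, function(w) {
    if (w >= total_time)    # no post-pulse period: the protocols coincide
      return(data.frame(width_min = w, tf1dt_mek = NA_real_,
                        tf1dt_wash = NA_real_, ratio = 1))
    mek <- endpoint(w, "mek_inhibition")
    wash <- endpoint(w, "washout")
    if (wash <= 0) stop("washout transcript endpoint is zero at width ", w)
    data.frame(width_min = w, tf1dt_mek = mek, tf1dt_wash = wash,
               ratio = mek / wash)
  })
  do.call(rbind, rows)
}
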