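# Stimulation protocols: square-wave GnRH pulse trains plus discrete
# interventions (ligand washout, MEK inhibitor). Amplitudes are stored in uM;
# the constructors accept molar units as used on dose axes.

MOLAR_TO_UM <- 1e6

#' Square-wave pulse protocol
#'
#' Low-level constructor. A protocol is a square wave of amplitude `p` (uM),
#' period `period`, pulse width `width` (pulses occupy the half-open interval
#' `[k*period, k*period + width)`), simulated over `[0, horizon]`, plus an
#' optional set of intervention events.
#'
#' @param p pulse amplitude, uM GnRH.
#' @param period pulse period, min.
#' @param width pulse width, min; `width == period` encodes constant
#'   stimulation.
#' @param horizon total simulated time, min.
#' @param events data frame with columns `time` (min) and `kind`
#'   (`"washout"` or `"mek_inhibition"`); at most one event of each kind.
#' @return an object of class `gnrh_protocol`.
#' @seealso [pulse_train()], [single_pulse()] for the protocols used in the
#'   pulse-decoding analyses.
#' @export
gnrh_protocol <- function(p, period, width, horizon,
                          events = data.frame(time = numeric(),
                                              kind = character())) {
  stopifnot(is.numeric(p), length(p) == 1, p >= 0,
            is.numeric(period), period > 0,
            is.numeric(width), width > 0,
            is.numeric(horizon), horizon > 0)
  if (width > period) stop("pulse width must not exceed the period")
  stopifnot(is.data.frame(events), all(c("time", "kind") %in% names(events)))
  if (nrow(events)) {
    if (!all(events$kind %in% c("washout", "mek_inhibition")))
      stop("event kind must be 'washout' or 'mek_inhibition'")
    if (anyDuplicated(events$kind))
      stop("at most one event of each kind")
    if (any(events$time < 0) || any(events$time > horizon))
      stop("event times must lie within [0, horizon]")
    events <- events[order(events$time), , drop = FALSE]
  }
  structure(list(p = p, period = period, width = width, horizon = horizon,
                 events = events),
            class = "gnrh_protocol")
}

#' @export
print.gnrh_protocol <- function(x, ...) {
  cat(sprintf(
    "GnRH protocol: %g uM pulses, width %g min, period %g min, horizon %g min\n",
    x$p, x$width, x$period, x$horizon))
  if (nrow(x$events))
    cat("events:", paste(sprintf("%s @ %g min", x$events$kind, x$events$time),
                         collapse = ", "), "\n")
  invisible(x)
}

.event_time <- function(protocol, kind) {
  ev <- protocol$events
  i <- which(ev$kind == kind)
  if (length(i)) ev$time[i] else Inf
}

#' GnRH input concentration at time t
#'
#' Evaluates the square-wave input: amplitude `p` while `t mod period < width`
#' (half-open pulses), 0 otherwise, and identically 0 from the washout time
#' onwards if the protocol carries a washout event.
#'
#' @param t time(s), min; must be non-negative.
#' @param protocol a [gnrh_protocol()].
#' @return GnRH concentration(s), uM.
#' @examples
#' prot <- pulse_train(1e-7, width = 5, interval = 60, horizon = 480)
#' gnrh_input(c(0.5, 5, 61), prot)   # 0.1, 0, 0.1
#' @export
gnrh_input <- function(t, protocol) {
  stopifnot(inherits(protocol, "gnrh_protocol"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  on_pulse <- (t %% protocol$period) < protocol$width
  washed <- t >= .event_time(protocol, "washout")
  ifelse(on_pulse & !washed, protocol$p, 0)
}

#' Pulsatile GnRH stimulation
#'
#' The pulse-train protocol of the frequency/width analyses: pulses of a given
#' width delivered at a fixed interval. Setting `interval == width` gives
#' constant stimulation (the maximal-frequency reference).
#'
#' @param amplitude_molar pulse amplitude in mol/L (e.g. `1e-7`).
#' @param width pulse width, min.
#' @param interval pulse interval (period), min; must be >= `width`.
#' @param horizon total simulated time, min.
#' @return a [gnrh_protocol()].
#' @examples
#' pulse_train(1e-7, width = 5, interval = 60, horizon = 480)
#' @export
pulse_train <- function(amplitude_molar, width, interval, horizon) {
  stopifnot(amplitude_molar >= 0, width > 0, horizon >= interval)
  if (width > interval) stop("pulse width must not exceed the interval")
  gnrh_protocol(p = amplitude_molar * MOLAR_TO_UM,
                period = interval, width = width, horizon = horizon)
}

#' Single GnRH pulse with defined termination
#'
#' One pulse starting at t = 0, terminated either by ligand washout (GnRH
#' removed at `width`; the input is then a one-pulse square wave) or by MEK
#' inhibition (the ligand stays per the square wave, but ERK phosphorylation
#' by MEK is blocked from `width` onwards).
#'
#' @param amplitude_molar pulse amplitude, mol/L.
#' @param width pulse width, min; must be < `horizon`.
#' @param horizon total simulated time, min.
#' @param termination `"washout"` or `"mek_inhibition"`.
#' @return a [gnrh_protocol()] carrying the corresponding event.
#' @examples
#' single_pulse(1e-7, width = 1, horizon = 30, termination = "washout")
#' @export
single_pulse <- function(amplitude_molar, width, horizon,
                         termination = c("washout", "mek_inhibition")) {
  termination <- match.arg(termination)
  stopifnot(amplitude_molar >= 0, width > 0)
  if (width >= horizon) stop("width must be smaller than horizon")
  gnrh_protocol(p = amplitude_molar * MOLAR_TO_UM,
                period = horizon + width, width = width, horizon = horizon,
                events = data.frame(time = width, kind = termination))
}

#' Receptor surface density to total receptor concentration
#'
#' Linear map from GnRH receptor sites per cell to the model's total receptor
#' concentration R0, anchored at 80,000 sites/cell = 0.1 uM (the
#' default-expression condition).
#'
#' @param sites_per_cell receptor sites per cell (> 0).
#' @return R0 in uM.
#' @examples
#' receptor_sites_to_R0(c(40000, 80000, 160000))  # 0.05 0.10 0.20
#' @export
receptor_sites_to_R0 <- function(sites_per_cell) {
  stopifnot(all(sites_per_cell > 0))
  0.1 * sites_per_cell / 80000
}
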