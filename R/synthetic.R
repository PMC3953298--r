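# Synthetic pseudo-experimental data with the structure of the live-cell
# measurements: per-cell ERK2-GFP nuclear:cytoplasmic ratio time courses
# normalized to t = 0, and dose-response endpoints normalized to the maximal
# dose. Noise is additive Gaussian on the measured scale; all cells share
# the deterministic model signal (the model describes the average cell, not
# cell-to-cell parameter variability).

#' Synthetic N:C ERK imaging traces
#'
#' Simulates the nuclear:cytoplasmic ERK ratio under a protocol, samples it
#' on a regular grid, adds i.i.d. Gaussian measurement noise per cell, and
#' normalizes each trace to its own value at t = 0 (as in ratio imaging).
#'
#' @param params a [gnrh_parameters()] object.
#' @param protocol a [gnrh_protocol()].
#' @param sample_interval sampling interval, min.
#' @param noise_sd measurement noise s.d. in raw ratio units (>= 0).
#' @param n_cells number of cells (replicate traces).
#' @param seed integer random seed.
#' @return data frame `(cell_id, time, value)` with attributes `protocol`,
#'   `noise_sd`, `n_cells`, `seed`.
#' @examples
#' tab <- generate_nc_traces(gnrh_parameters(),
#'                           single_pulse(1e-7, 5, 30), 2, 0.05, 3, seed = 1)
#' subset(tab, time == 0)$value   # all 1: traces are t0-normalized
#' @export
generate_nc_traces <- function(params, protocol, sample_interval = 1,
                               noise_sd = 0.05, n_cells = 1, seed = 1) {
  stopifnot(noise_sd >= 0, sample_interval > 0, n_cells >= 1)
  set.seed(seed)
  grid <- seq(0, protocol$horizon, by = sample_interval)
  traj <- simulate_protocol(params, protocol, output_step = sample_interval)
  nc <- traj$nc_erk[match(grid, traj$time)]
  cells <- lapply(seq_len(n_cells), function(cell) {
    noisy <- nc + stats::rnorm(length(nc), sd = noise_sd)
    data.frame(cell_id = cell, time = grid, value = noisy / noisy[1])
  })
  structure(do.call(rbind, cells),
            protocol = protocol, noise_sd = noise_sd, n_cells = n_cells,
            seed = seed, row.names = NULL)
}

#' Synthetic dose-response table
#'
#' For each GnRH dose, simulates a pulse train and computes the integrated
#' response: the baseline-subtracted area under the N:C ERK curve
#' (`observable = "NC_ERK"`) or the transcript endpoint at the horizon
#' (`observable = "TF1DT"`, the reporter-gene proxy). Gaussian noise with
#' s.d. `noise_sd` times the maximal raw response is added, then values are
#' normalized to the maximal-dose response (`value_norm`).
#'
#' @param params a [gnrh_parameters()] object.
#' @param doses_molar GnRH doses, mol/L (>= 0; 0 is the unstimulated
#'   control).
#' @param width,interval,horizon pulse-train geometry, min.
#' @param observable `"NC_ERK"` (integrated ratio) or `"TF1DT"` (endpoint).
#' @param noise_sd fractional noise s.d. (relative to the maximal raw
#'   response).
#' @param seed integer random seed.
#' @return data frame `(dose_molar, value, value_norm)` with attributes
#'   recording the design; `value` is the raw (noisy) response, `value_norm`
#'   the max-dose-normalized one. The per-dose protocols are attached as
#'   attribute `protocols`.
#' @export
generate_dose_response <- function(params, doses_molar, width = 5,
                                   interval = 60, horizon = 480,
                                   observable = c("NC_ERK", "TF1DT"),
                                   noise_sd = 0, seed = 1) {
  observable <- match.arg(observable)
  stopifnot(all(doses_molar >= 0), noise_sd >= 0)
  set.seed(seed)
  protocols <- lapply(doses_molar, function(d)
    pulse_train(d, width = width, interval = interval, horizon = horizon))
  names(protocols) <- paste0("dose_", format(doses_molar, scientific = TRUE))
  raw <- vapply(protocols, function(prot) {
    if (identical(observable, "NC_ERK")) {
      grid <- seq(0, horizon, by = .AUC_STEP)
      traj <- simulate_protocol(params, prot, output_step = .AUC_STEP)
      nc <- traj$nc_erk[match(grid, traj$time)]
      auc(grid, nc, baseline = nc[1])
    } else {
      traj <- simulate_protocol(params, prot, output_step = horizon)
      traj$TF1DT[nrow(traj)]
    }
  }, numeric(1))
  noisy <- raw + stats::rnorm(length(raw), sd = noise_sd * max(abs(raw)))
  imax <- which.max(doses_molar)
  if (noisy[imax] == 0) stop("maximal-dose response is zero")
  structure(data.frame(dose_molar = doses_molar, value = unname(noisy),
                       value_norm = unname(noisy / noisy[imax])),
            protocols = protocols, observable = observable,
            width = width, interval = interval, horizon = horizon,
            noise_sd = noise_sd, seed = seed, row.names = NULL)
}

#' Assemble fitting objectives from synthetic tables
#'
#' Converts N:C trace tables ([generate_nc_traces()]) and a dose-response
#' table ([generate_dose_response()]) into an [objective_set()]: replicate
#' cells are averaged per time point; dose-response rows become one record
#' per dose (raw scale). With `se_weights = TRUE` and more than one cell,
#' trace records are weighted by the inverse squared standard error of the
#' per-time cell mean; otherwise all weights are `weight`.
#'
#' @param nc_traces named list of trace tables; names are used as protocol
#'   ids.
#' @param dose_response optional dose-response table, or a named list of
#'   them (e.g. one ERK and one reporter curve); list names prefix the
#'   per-dose protocol ids.
#' @param weight default record weight.
#' @param se_weights use 1/SE^2 weights for trace records.
#' @return an [objective_set()].
#' @export
make_objectives <- function(nc_traces = list(), dose_response = NULL,
                            weight = 1, se_weights = FALSE) {
  records <- list()
  protocols <- list()
  for (id in names(nc_traces)) {
    tab <- nc_traces[[id]]
    prot <- attr(tab, "protocol")
    if (is.null(prot)) stop("trace table '", id, "' carries no protocol")
    agg <- stats::aggregate(value ~ time, data = tab, FUN = mean)
    w <- rep(weight, nrow(agg))
    if (se_weights && attr(tab, "n_cells") > 1) {
      sds <- stats::aggregate(value ~ time, data = tab, FUN = stats::sd)
      se2 <- sds$value^2 / attr(tab, "n_cells")
      w <- ifelse(se2 > 0, 1 / se2, weight)
    }
    keep <- agg$time > 0   # t = 0 is identically 1 by construction
    records[[id]] <- data.frame(protocol_id = id, observable = "NC_ERK_norm",
                                time = agg$time[keep], value = agg$value[keep],
                                weight = w[keep])
    protocols[[id]] <- prot
  }
  if (!is.null(dose_response)) {
    if (is.data.frame(dose_response))
      dose_response <- list(dose = dose_response)
    if (is.null(names(dose_response)) ||
        anyDuplicated(names(dose_response)))
      stop("dose-response tables must have unique names")
    for (nm in names(dose_response)) {
      tab <- dose_response[[nm]]
      dr_prot <- attr(tab, "protocols")
      obs <- attr(tab, "observable")
      if (is.null(dr_prot)) stop("dose-response table carries no protocols")
      names(dr_prot) <- paste0(nm, "_", names(dr_prot))
      records[[nm]] <- data.frame(
        protocol_id = names(dr_prot),
        observable = if (identical(obs, "NC_ERK")) "NC_ERK_auc" else "TF1DT",
        time = attr(tab, "horizon"),
        value = tab$value,
        weight = weight)
      protocols <- c(protocols, dr_prot)
    }
  }
  if (!length(records)) stop("no input tables supplied")
  objective_set(do.call(rbind, records), protocols)
}

#' Standard noiseless parameter-recovery objectives
#'
#' The fixed pseudo-observation design used to exercise the genetic
#' algorithm: normalized N:C ERK traces for the three stimulation regimes
#' the model was originally trained on (a 1-min washout pulse, a 10-min
#' washout pulse and constant stimulation, all at 1e-7 mol/L over 30 min,
#' sampled every 2 min) plus a 5-point integrated-N:C dose-response
#' (1e-11 to 1e-7 mol/L, 5-min pulses at 60-min intervals over 120 min).
#' All tables are noiseless, so [objective_fitness()] is exactly zero at
#' `params`.
#'
#' @param params the generating ("true") parameter set.
#' @return an [objective_set()].
#' @export
recovery_objectives <- function(params = gnrh_parameters()) {
  tr1 <- generate_nc_traces(params, single_pulse(1e-7, 1, 30),
                            sample_interval = 2, noise_sd = 0, n_cells = 1)
  tr10 <- generate_nc_traces(params, single_pulse(1e-7, 10, 30),
                             sample_interval = 2, noise_sd = 0, n_cells = 1)
  const <- generate_nc_traces(params, pulse_train(1e-7, 30, 30, 30),
                              sample_interval = 2, noise_sd = 0,
                              n_cells = 1)
  dr <- generate_dose_response(params,
                               c(1e-11, 1e-10, 1e-9, 1e-8, 1e-7),
                               width = 5, interval = 60, horizon = 120,
                               observable = "NC_ERK", noise_sd = 0)
  make_objectives(list(pulse_1min = tr1, pulse_10min = tr10,
                       constant = const),
                  dose_response = dr)
}
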