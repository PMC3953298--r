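# Flat-file configuration: parameters, a protocol and run options in one
# YAML or JSON document. Parsing is strict — unknown keys are rejected with
# the offending key named — so a typo can never silently fall back to a
# default.

.protocol_keys <- c("amplitude_molar", "width", "interval", "horizon",
                    "termination")
.option_keys <- c("output_step", "feedback")

.check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "))
}

#' Load a model configuration
#'
#' Reads a YAML (or JSON, by file extension) configuration with up to three
#' blocks: `parameters` (any subset of the model parameter names; the rest
#' take their default values), `protocol` (`amplitude_molar`, `width`,
#' `interval`, `horizon`, optional `termination` of `"washout"` or
#' `"mek_inhibition"`), and `options` (`output_step`, `feedback`).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return list with elements `params` ([gnrh_parameters()]), `protocol`
#'   ([gnrh_protocol()] or `NULL` if no protocol block), and `options`
#'   (named list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  .check_keys(cfg, c("parameters", "protocol", "options"), "top-level")

  par_block <- cfg$parameters
  if (is.null(par_block)) par_block <- list()
  .check_keys(par_block, .param_names, "parameter")

  opt <- cfg$options
  if (is.null(opt)) opt <- list()
  .check_keys(opt, .option_keys, "option")
  feedback <- if (is.null(opt$feedback)) "nuclear" else opt$feedback

  params <- do.call(gnrh_parameters,
                    c(lapply(par_block, as.numeric),
                      list(feedback = feedback)))

  protocol <- NULL
  if (!is.null(cfg$protocol)) {
    pb <- cfg$protocol
    .check_keys(pb, .protocol_keys, "protocol")
    needed <- setdiff(c("amplitude_molar", "width", "horizon"), names(pb))
    if (length(needed))
      stop("protocol block missing key(s): ", paste(needed, collapse = ", "))
    protocol <- if (!is.null(pb$termination) && pb$termination != "none")
      single_pulse(pb$amplitude_molar, pb$width, pb$horizon,
                   termination = pb$termination)
    else
      pulse_train(pb$amplitude_molar, pb$width,
                  interval = if (is.null(pb$interval)) pb$width
                             else pb$interval,
                  horizon = pb$horizon)
  }
  list(params = params, protocol = protocol, options = opt)
}

#' Save a model configuration
#'
#' Writes a configuration readable by [load_config()]. JSON keeps full
#' double precision and round-trips parameter sets exactly.
#'
#' @param params a [gnrh_parameters()] object.
#' @param path output path; format chosen by extension (`.json` or YAML).
#' @param protocol optional [gnrh_protocol()] built by [pulse_train()] or
#'   [single_pulse()] (trains and single terminated pulses are
#'   serializable).
#' @param options named list of run options.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path, protocol = NULL, options = list()) {
  stopifnot(inherits(params, "gnrh_params"))
  cfg <- list(parameters = as.list(stats::setNames(as.numeric(params),
                                                   .param_names)))
  if (!identical(attr(params, "feedback"), "nuclear"))
    options$feedback <- attr(params, "feedback")
  if (!is.null(protocol)) {
    pb <- list(amplitude_molar = protocol$p / MOLAR_TO_UM,
               width = protocol$width, horizon = protocol$horizon)
    if (nrow(protocol$events)) {
      if (nrow(protocol$events) > 1)
        stop("protocols with multiple events are not serializable")
      pb$termination <- protocol$events$kind[1]
    } else {
      pb$interval <- protocol$period
    }
    cfg$protocol <- pb
  }
  if (length(options)) cfg$options <- options
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Write a trajectory as tidy CSV with a provenance sidecar
#'
#' @param traj a trajectory from [simulate_protocol()].
#' @param path output CSV path; a `<path>.json` sidecar records parameters,
#'   protocol and package version.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "gnrh_trajectory"))
  out <- as.data.frame(traj)
  names(out)[names(out) == "time"] <- "time_min"
  utils::write.csv(out, path, row.names = FALSE)
  .write_sidecar(path, attr(traj, "params"), attr(traj, "protocol"))
  invisible(path)
}

.write_sidecar <- function(path, params, protocol, extra = list()) {
  meta <- c(list(
    package = "gnrhpulse",
    version = as.character(utils::packageVersion("gnrhpulse")),
    parameters = as.list(stats::setNames(as.numeric(params), .param_names)),
    feedback = attr(params, "feedback"),
    protocol = if (!is.null(protocol))
      list(p_uM = protocol$p, period_min = protocol$period,
           width_min = protocol$width, horizon_min = protocol$horizon,
           events = protocol$events)), extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(NULL)
}
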