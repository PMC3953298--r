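# Genetic-algorithm parameter estimation. Candidate parameter vectors are
# scored by weighted mean squared error against pseudo-observations
# (observable values at stated times under stated protocols); each
# generation every vector's fitted subset is perturbed multiplicatively,
# candidates are re-scored, and a new population is drawn by rank-weighted
# sampling with replacement. One elite (the best vector found so far) is
# carried through unmutated so the best-so-far fitness never increases.

.objective_observables <- c("NC_ERK", "NC_ERK_norm", "wholecell_ppERK",
                            "TF1DT", "NC_ERK_auc")

#' Pseudo-observation set for fitting
#'
#' Bundles observation records with the protocols that generate them. Each
#' record names a protocol, an observable, a time (for `NC_ERK_auc` the end
#' of the integration window), a target value and a positive weight.
#' Observables: `NC_ERK` (raw nuclear:cytoplasmic ratio), `NC_ERK_norm`
#' (ratio normalized to its value at t = 0, the imaging readout),
#' `wholecell_ppERK` (uM), `TF1DT` (transcript, uM, typically an endpoint),
#' and `NC_ERK_auc` (integrated baseline-subtracted ratio over `[0, time]`).
#'
#' @param records data frame with columns `protocol_id`, `observable`,
#'   `time`, `value` and optionally `weight` (default 1).
#' @param protocols named list of [gnrh_protocol()] objects; names must cover
#'   every `protocol_id`.
#' @return an object of class `gnrh_objectives`.
#' @export
objective_set <- function(records, protocols) {
  stopifnot(is.data.frame(records),
            all(c("protocol_id", "observable", "time", "value") %in%
                  names(records)))
  if (!"weight" %in% names(records)) records$weight <- 1
  if (any(records$weight <= 0)) stop("weights must be positive")
  bad <- setdiff(unique(records$observable), .objective_observables)
  if (length(bad))
    stop("unknown observable(s): ", paste(bad, collapse = ", "))
  missing <- setdiff(unique(records$protocol_id), names(protocols))
  if (length(missing))
    stop("records reference unknown protocol id(s): ",
         paste(missing, collapse = ", "))
  for (id in unique(records$protocol_id)) {
    h <- protocols[[id]]$horizon
    if (any(records$time[records$protocol_id == id] > h + 1e-9))
      stop("record times exceed the horizon of protocol ", id)
  }
  structure(list(records = records, protocols = protocols[
    intersect(names(protocols), unique(records$protocol_id))]),
    class = "gnrh_objectives")
}

#' @export
print.gnrh_objectives <- function(x, ...) {
  cat(sprintf("objective set: %d records over %d protocol(s)\n",
              nrow(x$records), length(x$protocols)))
  print(table(x$records$observable))
  invisible(x)
}

# Sampling grid used for AUC-type objective records; shared between the
# synthetic-data generator and the fitness evaluation so that noiseless
# objectives reproduce exactly.
.AUC_STEP <- 2

# Precompute everything fitness needs per protocol: the segment plan, the
# output times, and row/column index maps from records to the state matrix.
.compile_objectives <- function(objectives) {
  lapply(names(objectives$protocols), function(id) {
    prot <- objectives$protocols[[id]]
    rec <- objectives$records[objectives$records$protocol_id == id, ,
                              drop = FALSE]
    times <- rec$time
    has_auc <- any(rec$observable == "NC_ERK_auc")
    auc_times <- if (has_auc)
      unique(c(seq(0, max(rec$time[rec$observable == "NC_ERK_auc"]),
                   by = .AUC_STEP),
               max(rec$time[rec$observable == "NC_ERK_auc"])))
    else numeric()
    needs_t0 <- has_auc || any(rec$observable == "NC_ERK_norm")
    out_times <- sort(unique(c(if (needs_t0) 0, times, auc_times)))
    list(id = id, plan = .segment_plan(prot), out_times = out_times,
         records = rec, auc_times = auc_times)
  })
}

# N:C ratio and whole-cell ppERK from a state matrix (columns as in
# .state_names), vectorized over rows.
.matrix_observables <- function(states, C_cn) {
  s <- pmax(states, 0)
  cyto <- s[, "E_c"] + s[, "pE_c"] + s[, "ppE_c"]
  list(nc = (s[, "E_n"] + s[, "ppE_n"]) / cyto,
       pperk = (C_cn * s[, "ppE_c"] + s[, "ppE_n"]) / (C_cn + 1),
       tf1dt = s[, "TF1DT"])
}

.eval_fitness <- function(pv, fb_nuclear, compiled) {
  sq_sum <- 0
  w_sum <- 0
  for (cp in compiled) {
    out <- tryCatch(
      .simulate_core(pv, fb_nuclear, cp$plan, cp$out_times),
      error = function(e) NULL)
    if (is.null(out)) return(Inf)
    obs <- .matrix_observables(out[, .state_names, drop = FALSE], pv[31])
    tt <- out[, "time"]
    rec <- cp$records
    model <- numeric(nrow(rec))
    for (j in seq_len(nrow(rec))) {
      model[j] <- switch(
        rec$observable[j],
        NC_ERK = obs$nc[match(rec$time[j], tt)],
        NC_ERK_norm = obs$nc[match(rec$time[j], tt)] / obs$nc[match(0, tt)],
        wholecell_ppERK = obs$pperk[match(rec$time[j], tt)],
        TF1DT = obs$tf1dt[match(rec$time[j], tt)],
        NC_ERK_auc = {
          sel <- match(cp$auc_times[cp$auc_times <= rec$time[j] + 1e-9], tt)
          auc(tt[sel], obs$nc[sel], baseline = obs$nc[match(0, tt)])
        })
    }
    if (anyNA(model)) return(Inf)
    sq_sum <- sq_sum + sum(rec$weight * (model - rec$value)^2)
    w_sum <- w_sum + sum(rec$weight)
  }
  sq_sum / w_sum
}

#' Weighted mean squared error of a parameter set against objectives
#'
#' Simulates every protocol referenced by the objective set and returns the
#' weighted mean of squared deviations between model observables and target
#' values. Solver failure yields `Inf` (the candidate is culled).
#'
#' @param params a [gnrh_parameters()] object.
#' @param objectives an [objective_set()].
#' @return non-negative scalar (weighted MSE), or `Inf`.
#' @export
objective_fitness <- function(params, objectives) {
  stopifnot(inherits(objectives, "gnrh_objectives"))
  compiled <- .compile_objectives(objectives)
  fb <- as.numeric(identical(attr(params, "feedback"), "nuclear"))
  .eval_fitness(as.numeric(params), fb, compiled)
}

#' Mutate the fitted parameter subset
#'
#' Each parameter in the fitted subset is multiplied by `1 + scale * eps`
#' with `eps` i.i.d. standard normal (default scale 0.1), then clipped at a
#' positivity floor of 1e-12. Parameters outside the fitted subset are never
#' changed. Uses the R random number generator (seed it for reproducibility).
#'
#' @param params a [gnrh_parameters()] object.
#' @param scale mutation scale (standard deviation of the relative
#'   perturbation).
#' @return a mutated `gnrh_params` object.
#' @export
mutate_parameters <- function(params, scale = 0.1) {
  flagged <- fitted_parameters(params)
  out <- unclass(params)
  eps <- stats::rnorm(length(flagged))
  out[flagged] <- pmax(out[flagged] * (1 + scale * eps), 1e-12)
  .params_from_vector(out, params)
}

#' Rank-based selection probabilities
#'
#' The best-fitting vector (smallest fitness) of N receives rank weight N,
#' the worst weight 1; probabilities are weights over their sum. Ties are
#' broken by input order.
#'
#' @param fitnesses numeric vector of fitness (MSE) values.
#' @return selection probabilities summing to 1.
#' @examples
#' selection_probabilities(c(0.1, 0.9))  # 2/3, 1/3
#' @export
selection_probabilities <- function(fitnesses) {
  n <- length(fitnesses)
  w <- n + 1 - rank(fitnesses, ties.method = "first")
  w / sum(w)
}

#' Rank-weighted resampling of a population
#'
#' Samples `length(population)` members with replacement, with probability
#' proportional to fitness rank (see [selection_probabilities()]).
#'
#' @param population list of parameter sets (or any objects).
#' @param fitnesses fitness of each member (smaller is better).
#' @return resampled population (a list of the same length).
#' @export
select_population <- function(population, fitnesses) {
  stopifnot(length(population) >= 1,
            length(fitnesses) == length(population))
  if (length(population) == 1) return(population)
  idx <- sample.int(length(population), length(population), replace = TRUE,
                    prob = selection_probabilities(fitnesses))
  population[idx]
}

#' Fit the flagged parameter subset by a genetic algorithm
#'
#' The population starts as `pop_size` copies of `init`. Each generation the
#' fitted subset of every vector is mutated ([mutate_parameters()]),
#' candidates are scored ([objective_fitness()]), the best-so-far vector
#' replaces the worst candidate (elitism), and a new population is drawn by
#' rank-weighted sampling with replacement. Fully reproducible from `seed`.
#'
#' @param objectives an [objective_set()].
#' @param init a [gnrh_parameters()] object used to seed the population (its
#'   `fitted` attribute defines the subset being estimated).
#' @param generations number of generations (>= 1).
#' @param pop_size population size (>= 2).
#' @param seed integer random seed.
#' @param scale mutation scale passed to [mutate_parameters()].
#' @return an object of class `gnrh_fit`: list with `best` (the best-ever
#'   `gnrh_params`), `best_fitness`, `history` (best-so-far fitness per
#'   generation, non-increasing), `seed`, `pop_size`, `generations`.
#' @export
fit_parameters <- function(objectives, init = gnrh_parameters(),
                           generations = 150, pop_size = 50, seed = 1,
                           scale = 0.1) {
  stopifnot(inherits(objectives, "gnrh_objectives"),
            inherits(init, "gnrh_params"),
            generations >= 1, pop_size >= 2)
  set.seed(seed)
  compiled <- .compile_objectives(objectives)
  fb <- as.numeric(identical(attr(init, "feedback"), "nuclear"))
  flag_idx <- match(fitted_parameters(init), .param_names)
  nf <- length(flag_idx)

  pop <- matrix(rep(as.numeric(init), pop_size), nrow = length(.param_names))
  best_v <- as.numeric(init)
  best_f <- .eval_fitness(best_v, fb, compiled)
  history <- numeric(generations)

  for (g in seq_len(generations)) {
    eps <- matrix(stats::rnorm(nf * pop_size), nrow = nf)
    pop[flag_idx, ] <- pmax(pop[flag_idx, ] * (1 + scale * eps), 1e-12)
    f <- vapply(seq_len(pop_size),
                function(j) .eval_fitness(pop[, j], fb, compiled),
                numeric(1))
    if (all(!is.finite(f)) && !is.finite(best_f))
      stop("all candidates failed to simulate in generation ", g)
    # elitism: the best-so-far vector replaces the worst candidate
    worst <- which.max(ifelse(is.finite(f), f, Inf))
    pop[, worst] <- best_v
    f[worst] <- best_f
    gen_best <- which.min(f)
    if (f[gen_best] < best_f) {
      best_f <- f[gen_best]
      best_v <- pop[, gen_best]
    }
    history[g] <- best_f
    idx <- sample.int(pop_size, pop_size, replace = TRUE,
                      prob = selection_probabilities(f))
    pop <- pop[, idx, drop = FALSE]
  }

  structure(list(best = .params_from_vector(best_v, init),
                 best_fitness = best_f, history = history, seed = seed,
                 pop_size = pop_size, generations = generations),
            class = "gnrh_fit")
}

#' @export
print.gnrh_fit <- function(x, ...) {
  cat(sprintf(
    "GA fit: pop %d x %d generations (seed %d), best MSE %.4g\n",
    x$pop_size, x$generations, x$seed, x$best_fitness))
  flagged <- fitted_parameters(x$best)
  print(stats::setNames(as.numeric(unclass(x$best)[flagged]), flagged))
  invisible(x)
}
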