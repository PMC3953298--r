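# A small, fast objective set shared by the fitting tests: one short washout
# pulse, normalized N:C records every 5 min.
tiny_objectives <- function(params = default_params) {
  tr <- generate_nc_traces(params, single_pulse(1e-7, 1, 20),
                           sample_interval = 5, noise_sd = 0, n_cells = 1,
                           seed = 1)
  make_objectives(list(pulse = tr))
}

test_that("mutation perturbs only the fitted subset with the stated law", {
  p <- default_params
  flagged <- fitted_parameters(p)
  unflagged <- setdiff(names(unclass(p)), flagged)

  set.seed(1)
  m0 <- mutate_parameters(p, scale = 0)
  expect_identical(unclass(m0), unclass(p))

  set.seed(2)
  ratios <- replicate(1e4, {
    m <- mutate_parameters(p)
    expect_identical(unclass(m)[unflagged], unclass(p)[unflagged])
    unclass(m)[["k2"]] / unclass(p)[["k2"]]
  })
  # theta_new/theta = 1 + 0.1 eps: mean 1, sd 0.1 (law of large numbers)
  expect_lt(abs(mean(ratios) - 1), 0.005)
  expect_lt(abs(sd(ratios) - 0.1), 0.005)
  # positivity floor
  tiny <- gnrh_parameters(R0 = 1e-12)
  set.seed(3)
  for (i in 1:50) expect_gte(mutate_parameters(tiny)[["R0"]], 1e-12)
})

test_that("rank selection gives the stated probabilities and is stable under
           ties", {
  expect_equal(selection_probabilities(c(0.1, 0.9)), c(2 / 3, 1 / 3))
  expect_equal(selection_probabilities(c(0.9, 0.1)), c(1 / 3, 2 / 3))
  # ties broken by input order: first of equals gets the larger weight
  expect_equal(selection_probabilities(c(0.5, 0.5)), c(2 / 3, 1 / 3))
  expect_equal(sum(selection_probabilities(runif(7))), 1)
  pop1 <- list(default_params)
  expect_identical(select_population(pop1, 0.3), pop1)
  set.seed(4)
  sel <- select_population(as.list(1:5), c(5, 4, 3, 2, 1))
  expect_length(sel, 5)
})

test_that("fitness is zero at the generating parameters and scales as a
           weighted mean", {
  p <- default_params
  obj <- tiny_objectives(p)
  expect_lt(objective_fitness(p, obj), 1e-12)

  # one record, model - target = 0.5 -> MSE 0.25
  prot <- single_pulse(1e-7, 1, 20)
  tr <- simulate_protocol(p, prot, output_step = 5)
  model_val <- tr$pperk_wholecell[tr$time == 10]
  rec <- data.frame(protocol_id = "a", observable = "wholecell_ppERK",
                    time = 10, value = model_val - 0.5, weight = 1)
  one <- objective_set(rec, list(a = prot))
  expect_equal(objective_fitness(p, one), 0.25, tolerance = 1e-6)

  # doubling all weights leaves the weighted mean unchanged
  rec2 <- obj$records
  rec2$weight <- rec2$weight * 2
  obj2 <- objective_set(rec2, obj$protocols)
  perturbed <- gnrh_parameters(k_imp = 0.3)
  expect_equal(objective_fitness(perturbed, obj),
               objective_fitness(perturbed, obj2))
})

test_that("objective sets validate their records", {
  prot <- single_pulse(1e-7, 1, 20)
  base <- data.frame(protocol_id = "a", observable = "NC_ERK", time = 5,
                     value = 1, weight = 1)
  expect_s3_class(objective_set(base, list(a = prot)), "gnrh_objectives")
  bad_w <- transform(base, weight = 0)
  expect_error(objective_set(bad_w, list(a = prot)), "positive")
  bad_t <- transform(base, time = 25)
  expect_error(objective_set(bad_t, list(a = prot)), "horizon")
  bad_o <- transform(base, observable = "banana")
  expect_error(objective_set(bad_o, list(a = prot)), "banana")
  expect_error(objective_set(base, list(b = prot)), "unknown protocol")
})

test_that("the genetic algorithm is reproducible, monotone in best-so-far,
           and invariant at mutation scale zero", {
  obj <- tiny_objectives()
  init <- gnrh_parameters(k_imp = 0.4, k_exp = 1.5)  # off-truth start
  f1 <- fit_parameters(obj, init, generations = 6, pop_size = 6, seed = 9)
  f2 <- fit_parameters(obj, init, generations = 6, pop_size = 6, seed = 9)
  expect_identical(f1, f2)
  expect_true(all(diff(f1$history) <= 0))
  expect_lt(f1$best_fitness, objective_fitness(init, obj))

  frozen <- fit_parameters(obj, init, generations = 3, pop_size = 4,
                           seed = 1, scale = 0)
  expect_identical(unclass(frozen$best), unclass(init))

  # starting at the generating truth, fitness is already ~0
  at_truth <- fit_parameters(obj, default_params, generations = 1,
                             pop_size = 4, seed = 2)
  expect_lt(at_truth$best_fitness, 1e-12)
})
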