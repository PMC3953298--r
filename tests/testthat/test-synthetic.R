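test_that("noiseless traces reproduce the normalized model signal exactly", {
  p <- default_params
  prot <- single_pulse(1e-7, 5, 30)
  tab <- generate_nc_traces(p, prot, sample_interval = 2, noise_sd = 0,
                            n_cells = 1, seed = 1)
  tr <- simulate_protocol(p, prot, output_step = 2)
  nc <- tr$nc_erk[match(tab$time, tr$time)]
  expect_equal(tab$value, nc / nc[1])
})

test_that("traces are t0-normalized per cell and reproducible from the
           seed", {
  prot <- single_pulse(1e-7, 5, 30)
  tab <- generate_nc_traces(default_params, prot, 5, 0.05, 4, seed = 3)
  expect_equal(tab$value[tab$time == 0], rep(1, 4))
  tab2 <- generate_nc_traces(default_params, prot, 5, 0.05, 4, seed = 3)
  expect_identical(tab, tab2)
  tab3 <- generate_nc_traces(default_params, prot, 5, 0.05, 4, seed = 4)
  expect_false(identical(tab$value, tab3$value))
})

test_that("the many-cell mean concentrates on the noiseless trace", {
  p <- default_params
  prot <- single_pulse(1e-7, 5, 30)
  noise_sd <- 0.05
  n <- 500
  tab <- generate_nc_traces(p, prot, 5, noise_sd, n, seed = 5)
  clean <- generate_nc_traces(p, prot, 5, 0, 1, seed = 1)
  m <- aggregate(value ~ time, tab, mean)
  # each trace is divided by its own noisy t0 (resting N:C = 0.8), which
  # scales the noise by 1/0.8 and adds a correlated ratio term ~ value/0.8
  nc0 <- 0.8
  tol <- 3 * noise_sd / sqrt(n) * (1 + max(clean$value)) / nc0
  expect_lt(max(abs(m$value - clean$value[match(m$time, clean$time)])), tol)
})

test_that("dose-response is monotone in dose, zero at dose zero and
           normalized at the top dose", {
  p <- default_params
  doses <- c(0, 1e-9, 1e-7)
  dr <- generate_dose_response(p, doses, width = 5, interval = 60,
                               horizon = 120, observable = "NC_ERK",
                               noise_sd = 0, seed = 1)
  expect_equal(dr$value[dr$dose_molar == 0], 0, tolerance = 1e-8)
  expect_equal(dr$value_norm[dr$dose_molar == 1e-7], 1)
  expect_lt(dr$value_norm[dr$dose_molar == 1e-9],
            dr$value_norm[dr$dose_molar == 1e-7])
  rep_dr <- generate_dose_response(p, doses, width = 5, interval = 60,
                                   horizon = 120, observable = "TF1DT",
                                   noise_sd = 0, seed = 1)
  expect_true(all(diff(rep_dr$value) > 0))
})

test_that("objectives assembled from noiseless tables give zero fitness at
           the generating parameters", {
  p <- default_params
  tr <- generate_nc_traces(p, single_pulse(1e-7, 1, 20), 5, 0, 1, seed = 1)
  dr <- generate_dose_response(p, c(1e-9, 1e-7), width = 5, interval = 60,
                               horizon = 120, observable = "NC_ERK",
                               noise_sd = 0, seed = 1)
  rep_dr <- generate_dose_response(p, c(1e-9, 1e-7), width = 5,
                                   interval = 60, horizon = 120,
                                   observable = "TF1DT", noise_sd = 0,
                                   seed = 1)
  obj <- make_objectives(list(pulse = tr),
                         dose_response = list(erk = dr, rep = rep_dr))
  expect_lt(objective_fitness(p, obj), 1e-10)
  expect_true(all(obj$records$weight == 1))
})

test_that("standard-error weights scale like n over the noise variance", {
  p <- default_params
  noise_sd <- 0.05
  n <- 100
  tab <- generate_nc_traces(p, single_pulse(1e-7, 1, 20), 5, noise_sd, n,
                            seed = 6)
  obj <- make_objectives(list(pulse = tab), se_weights = TRUE)
  w <- obj$records$weight
  # per-point variance of the t0-normalized trace: the t0 ratio scales the
  # noise by 1/NC(0) and adds a correlated term, so the variance is about
  # noise_sd^2 * (1 + r^2) / NC(0)^2 with r = value/NC(0) near 1
  expected <- n / (noise_sd^2 * 2 / 0.8^2)
  expect_gt(median(w), expected / 3)
  expect_lt(median(w), expected * 3)
})
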