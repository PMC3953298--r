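test_that("zero-amplitude protocols stay at rest and phospho-species stay
           zero", {
  p <- default_params
  tr <- simulate_protocol(p, pulse_train(0, 5, 60, 240), output_step = 5)
  rest <- resting_state(p)
  for (nm in names(rest))
    expect_lt(max(abs(tr[[nm]] - rest[[nm]])), 1e-9)
  expect_true(all(abs(tr$pperk_wholecell) < 1e-12))
})

test_that("trajectories conserve ERK amount and include every pulse edge", {
  p <- default_params
  prot <- pulse_train(1e-7, 5, 60, 480)
  tr <- simulate_protocol(p, prot, output_step = 0.5)
  res <- (tr$E_c + tr$pE_c + tr$ppE_c) +
    (tr$E_n + tr$ppE_n) / p[["C_cn"]] - p[["ERK_tot"]]
  expect_lt(max(abs(res)), 1e-6)
  edges <- c(seq(0, 420, by = 60), seq(5, 425, by = 60))
  expect_true(all(edges %in% tr$time))
  expect_true(all(diff(tr$time) > 0))
  expect_equal(tr$gnrh, gnrh_input(tr$time, prot))
})

test_that("simulation is deterministic and stable under grid refinement", {
  p <- default_params
  prot <- single_pulse(1e-7, 5, 60)
  a <- simulate_protocol(p, prot, output_step = 1)
  b <- simulate_protocol(p, prot, output_step = 1)
  expect_identical(a, b)
  fine <- simulate_protocol(p, prot, output_step = 0.5)
  shared <- match(a$time, fine$time)
  for (col in c("pperk_wholecell", "nc_erk"))
    expect_lt(max(abs(a[[col]] - fine[[col]][shared])) /
                max(abs(a[[col]])), 1e-6)
})

test_that("non-integer pulse widths are classified correctly at the edges", {
  # regression: floating-point modulo at an edge (60.9 %% 60 < 0.9) must not
  # leak the pulse amplitude into the following off-segment
  tr <- simulate_protocol(default_params, pulse_train(1e-7, 0.9, 60, 180),
                          output_step = 0.5)
  expect_lt(tr$HR[tr$time == 30], 1e-6)
  expect_lt(tr$HR[tr$time == 90], 1e-6)
  expect_lt(auc(tr$time, tr$HR), 3 * 0.1 * (0.9 + 0.25))
})

test_that("whole-cell ppERK is the volume-weighted mean and N:C needs
           cytosolic ERK", {
  p <- default_params
  s <- resting_state(p)
  expect_equal(unname(observables(s, p)[["NC_ERK"]]), 0.8)
  s[["ppE_c"]] <- 0.3
  s[["ppE_n"]] <- 0.3
  expect_equal(unname(observables(s, p)[["wholecell_ppERK"]]), 0.3)
  s0 <- s
  s0[c("E_c", "pE_c", "ppE_c")] <- 0
  expect_error(observables(s0, p), "cytosolic")
})

test_that("fixed-step reference integration agrees with the adaptive
           solver", {
  p <- default_params
  prot <- single_pulse(1e-7, 5, 60)
  orc <- oracle_simulate(p, prot, step = 0.002, output_step = 5)
  tr <- simulate_protocol(p, prot, output_step = 5)
  shared <- intersect(orc$time, tr$time)
  a <- as.matrix(orc[match(shared, orc$time), -1])
  b <- as.matrix(tr[match(shared, tr$time), 2:11])
  expect_lt(max(abs(a - b)) / max(abs(b)), 1e-4)
})

test_that("the reference integrator converges at fourth order", {
  p <- default_params
  prot <- single_pulse(1e-9, 5, 60)   # gentle input: asymptotic regime
  ref <- oracle_simulate(p, prot, step = 0.00125, output_step = 10)
  err <- vapply(c(0.04, 0.02), function(h) {
    o <- oracle_simulate(p, prot, step = h, output_step = 10)
    max(abs(as.matrix(o[, -1]) - as.matrix(ref[, -1])))
  }, numeric(1))
  expect_gt(err[1] / err[2], 10)   # ~16-fold per halving
  expect_lt(err[1] / err[2], 25)
})

test_that("N:C responses are reproducible from pulse to pulse at 60-min
           intervals", {
  tr <- simulate_protocol(default_params, pulse_train(1e-7, 5, 60, 480),
                          output_step = 0.25)
  peaks <- vapply(0:7, function(k)
    max(tr$nc_erk[tr$time >= k * 60 & tr$time < (k + 1) * 60]), numeric(1))
  expect_lt((max(peaks) - min(peaks)) / max(peaks), 0.05)
})

test_that("ppERK peaks after the end of a short washout pulse", {
  tr <- simulate_protocol(default_params, single_pulse(1e-7, 1, 30),
                          output_step = 0.1)
  expect_gt(tr$time[which.max(tr$pperk_wholecell)], 1)
})
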