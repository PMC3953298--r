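test_that("algebraic MEK activation saturates with the expected half-point", {
  p <- default_params
  expect_equal(mek_active(0, p), 0)
  expect_equal(mek_active(p[["K_MM_MEK"]], p), p[["MEK_tot"]] / 2)
  expect_lt(abs(mek_active(1e6, p) - p[["MEK_tot"]]), 1e-6)
  E <- seq(0, 2, by = 0.01)
  v <- mek_active(E, p)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v <= p[["MEK_tot"]]))
  expect_error(mek_active(-0.1, p), "non-negative")
})

test_that("phosphorylation fluxes vanish without substrate and respect the
           MEK-inhibition contract", {
  p <- default_params
  zero <- c(HR = 0, GQ = 1, E = 0.5, E_c = 0, pE_c = 0, ppE_c = 0,
            E_n = 0, ppE_n = 0, TF1 = 0, TF1DT = 0)
  expect_equal(unname(phospho_fluxes(zero, ppMEK = 0.3, p)), rep(0, 5))

  # nuclear dephosphorylation at half-saturation: kcat_5 * MKP_n / 2
  s <- zero; s[["ppE_n"]] <- p[["kd_ppEn"]]
  expect_equal(phospho_fluxes(s, 0, p)[["v5"]],
               p[["kcat_5"]] * p[["MKP_n"]] / 2)

  busy <- random_states(1)[[1]]
  v <- phospho_fluxes(busy, 0.3, p)
  vi <- phospho_fluxes(busy, 0.3, p, mek_inhibited = TRUE)
  expect_equal(unname(vi[c("v1", "v2")]), c(0, 0))
  expect_equal(vi[c("v3", "v4", "v5")], v[c("v3", "v4", "v5")])
  expect_true(all(v >= 0))
})

test_that("each flux is monotone non-decreasing in its substrate", {
  p <- default_params
  substrate <- c(v1 = "E_c", v2 = "pE_c", v3 = "ppE_c", v4 = "pE_c",
                 v5 = "ppE_n")
  for (s0 in random_states(20)) {
    for (f in names(substrate)) {
      lo <- s0
      hi <- s0
      hi[[substrate[[f]]]] <- hi[[substrate[[f]]]] * 1.5 + 0.01
      expect_gte(phospho_fluxes(hi, 0.3, p)[[f]],
                 phospho_fluxes(lo, 0.3, p)[[f]])
    }
  }
})

test_that("the resting state is a fixed point with the closed-form ERK
           partition", {
  p <- default_params
  s <- resting_state(p)
  expect_equal(s[["E_n"]] / s[["E_c"]],
               p[["C_cn"]] * p[["k_imp"]] / p[["k_exp"]])
  expect_equal(s[["E_c"]], 0.9 / (1 + 0.2 / 0.75))
  expect_equal(s[["E_n"]], p[["C_cn"]] * 0.2 / 0.75 * s[["E_c"]])
  zero_prot <- pulse_train(0, 5, 60, 480)
  d <- gnrh_rhs(10, s, p, zero_prot)
  expect_lt(max(abs(d)), 1e-9)
  expect_equal(conservation_residuals(s, p)$erk_residual, 0)
})

test_that("receptor occupancy has the mass-action equilibria", {
  p <- default_params
  hr_star <- function(G) p[["R0"]] * p[["k1"]] * G /
    (p[["k1"]] * G + p[["k_minus1"]])
  expect_equal(hr_star(0.1), 0.1 * 500 / 505)
  expect_equal(hr_star(1e-3), 0.05)   # half-occupancy at Kd = 1 nM
  s <- resting_state(p)
  s[["HR"]] <- hr_star(0.1)
  d <- gnrh_rhs(0.5, s, p, pulse_train(1e-7, 5, 60, 480))
  expect_lt(abs(d[["HR"]]), 1e-12)
})

test_that("ERK amount is conserved analytically by the right-hand side", {
  p <- default_params
  prot <- pulse_train(1e-7, 5, 60, 480)
  for (s in random_states(1000)) {
    d <- gnrh_rhs(2, s, p, prot)
    ddt <- d[["E_c"]] + d[["pE_c"]] + d[["ppE_c"]] +
      (d[["E_n"]] + d[["ppE_n"]]) / p[["C_cn"]]
    expect_lt(abs(ddt), 1e-12 * max(abs(d)))
  }
})

test_that("the fast positional right-hand side matches the reference", {
  p <- default_params
  prot <- pulse_train(1e-7, 5, 60, 480)
  pv <- as.numeric(p)
  for (s in random_states(50)) {
    for (tt in c(0.5, 10)) {
      ref <- gnrh_rhs(tt, s, p, prot)
      fast <- gnrhpulse:::.rhs_fast(unname(s), pv, gnrh_input(tt, prot),
                                    FALSE, TRUE)
      expect_equal(unname(ref), fast)
    }
  }
  pc <- gnrh_parameters(feedback = "cytosolic")
  s <- random_states(1)[[1]]
  expect_equal(unname(gnrh_rhs(0.5, s, pc, prot)),
               gnrhpulse:::.rhs_fast(unname(s), pv, 0.1, FALSE, FALSE))
})

test_that("conservation diagnostics flag violations", {
  p <- default_params
  s <- resting_state(p)
  s[["ppE_c"]] <- -0.01
  r <- conservation_residuals(s, p)
  expect_true(any(grepl("ppE_c", r$violations)))
  s2 <- resting_state(p)
  s2[["HR"]] <- p[["R0"]] * 2
  expect_true("HR > R0" %in% conservation_residuals(s2, p)$violations)
})

test_that("non-finite states are rejected by the right-hand side", {
  s <- resting_state(default_params)
  s[["E"]] <- NaN
  expect_error(gnrh_rhs(0, s, default_params, pulse_train(0, 5, 60, 60)),
               "finite")
})
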