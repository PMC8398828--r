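test_that("with all rates zero and no sampling the state is frozen", {
  des <- design_nosampling()
  ts <- simulate_kinetics(des, one_compound(conc = 100),
                          kinetic_params("cmpA"))
  expect_equal(ts$donor_conc, rep(100, 7))
  expect_equal(ts$membrane_amount, rep(0, 7))
  expect_equal(ts$acceptor_conc, rep(0, 7))
})

test_that("donor hydrolysis follows the closed form and feeds the product mole-for-mole", {
  des <- design_nosampling()
  cmp <- dplyr::bind_rows(one_compound("gly", conc = 100),
                          one_compound("agl", conc = 0, mz = 255.0652, rt = 6.9))
  k <- 0.01
  kin <- kinetic_params(c("gly", "agl"), k_hydrolysis = c(k, 0),
                        hydrolysis_product = c("agl", NA))
  ts <- simulate_kinetics(des, cmp, kin)
  gly <- ts[ts$compound_id == "gly", ]
  agl <- ts[ts$compound_id == "agl", ]
  expect_equal(gly$donor_conc, 100 * exp(-k * gly$time), tolerance = 1e-9)
  # product appears exactly where the precursor went
  expect_equal(agl$donor_conc, 100 - gly$donor_conc, tolerance = 1e-9)
  expect_equal(agl$converted_in, gly$converted_out, tolerance = 1e-12)
})

test_that("linear-regime acceptor accumulation matches the analytic slope and a reference integrator", {
  des <- design_nosampling()
  cmp <- one_compound(conc = 100)
  kin <- kinetic_params("cmpA", papp_true = 1e-6)
  ts <- simulate_kinetics(des, cmp, kin)
  acc100 <- ts$acceptor_conc[ts$time == 100]
  # analytic slope P*A*C0/V_A in the acceptor << donor regime
  slope <- 1e-6 * 60 * 1.26 * 100 / 7
  expect_equal(acc100, slope * 100, tolerance = 0.005)
  expect_equal(acc100, 0.108, tolerance = 0.005)

  # independent oracle: adaptive LSODA on the same two-compartment ODE
  skip_if_not_installed("deSolve")
  rhs <- function(t, y, p) {
    kd <- 1e-6 * 60 * 1.26 / 7
    list(c(-kd * y[1], kd * y[1] * 7 / 7))
  }
  ref <- deSolve::lsoda(c(100, 0), c(0, 100), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_equal(acc100, as.numeric(ref[2, 3]), tolerance = 1e-6)
  expect_equal(ts$donor_conc[ts$time == 100], as.numeric(ref[2, 2]),
               tolerance = 1e-6)
})

test_that("sampling events apply the exact dilution or stock-replacement formulas", {
  times <- c(0, 10, 20, 40, 60, 80, 100)
  des_buffer <- chamber_design(donor_aliquot = 0.2, acceptor_aliquot = 0.4,
                               sampling_times = times,
                               donor_replacement = "fresh_buffer")
  cmp <- one_compound(conc = 100)
  ts <- simulate_kinetics(des_buffer, cmp, kinetic_params("cmpA"))
  # n-th recorded donor concentration has seen n-1 dilution events
  expect_equal(ts$donor_conc, 100 * ((7 - 0.2) / 7)^(seq_along(times) - 1))

  des_stock <- chamber_design(donor_aliquot = 0.2, acceptor_aliquot = 0.4,
                              sampling_times = times,
                              donor_replacement = "stock_solution")
  ts2 <- simulate_kinetics(des_stock, cmp, kinetic_params("cmpA"))
  expect_equal(ts2$donor_conc, rep(100, length(times)))
})

test_that("mass balance closes within 0.1% at every sampling time", {
  for (name in c("pure_daidzin", "extract")) {
    sc <- get_scenario(name)
    truth <- simulate_kinetics(sc$design, sc$compounds, sc$kinetics)
    expect_lt(mass_balance_error(truth, sc$design), 0.001)
  }
})

test_that("acceptor amount at 100 min is strictly increasing in permeability", {
  des <- design_extract()
  cmp <- one_compound(conc = 100)
  acc <- vapply(c(0.5, 1, 2.5, 5, 10) * 1e-6, function(p) {
    ts <- simulate_kinetics(des, cmp, kinetic_params("cmpA", papp_true = p))
    tail(ts$acceptor_conc, 1)
  }, 1)
  expect_true(all(diff(acc) > 0))
})

test_that("measurement is proportional, censored at the LOD floor, and seed-reproducible", {
  des <- chamber_design(sampling_times = c(0, 100), n_replicates = 2)
  cmp <- one_compound(conc = 10)
  truth <- simulate_kinetics(des, cmp, kinetic_params("cmpA"))
  tab <- apply_measurement(truth, des, measurement_model(1e4, 0, 1e3),
                           seed = 3)
  expect_equal(tab$donor_t0_r1, 1e5)

  # concentration below lod_height / response_factor is absent
  cmp_low <- one_compound(conc = 0.05)
  truth_low <- simulate_kinetics(des, cmp_low, kinetic_params("cmpA"))
  tab_low <- apply_measurement(truth_low, des, measurement_model(1e4, 0, 1e3),
                               seed = 3)
  expect_true(is.na(tab_low$donor_t0_r1))

  noisy <- measurement_model(1e4, noise_cv = 0.1, lod_height = 1e3)
  t1 <- apply_measurement(truth, des, noisy, seed = 11)
  t2 <- apply_measurement(truth, des, noisy, seed = 11)
  t3 <- apply_measurement(truth, des, noisy, seed = 12)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
})

test_that("TEER traces decay, cross thresholds by construction, and reproduce under seed", {
  des <- chamber_design(n_replicates = 2)
  flat <- simulate_teer(des, baseline = 40, decay_rate = 0, noise_sd = 0)
  expect_true(all(flat$resistance == 40))

  # decay chosen so the trace ends below the 15 Ohm cm2 viability floor
  k <- log(20 / 14) / 100
  low <- simulate_teer(des, baseline = 20, decay_rate = k, noise_sd = 0)
  expect_lt(min(low$resistance), 15)

  n1 <- simulate_teer(des, 40, 1e-3, noise_sd = 2, seed = 5)
  n2 <- simulate_teer(des, 40, 1e-3, noise_sd = 2, seed = 5)
  expect_identical(n1, n2)
  expect_true(all(n1$resistance >= 0))
})

test_that("unknown product ids and cyclic product graphs are rejected", {
  des <- design_nosampling()
  cmp <- one_compound(conc = 100)
  kin <- kinetic_params("cmpA", k_hydrolysis = 0.01,
                        hydrolysis_product = "nope")
  expect_error(simulate_kinetics(des, cmp, kin), "unknown product")
  expect_error(
    kinetic_params(c("a", "b"), k_hydrolysis = c(0.1, 0.1),
                   hydrolysis_product = c("b", "a")),
    "cyclic"
  )
})
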