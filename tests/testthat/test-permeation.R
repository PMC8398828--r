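test_that("the cumulative-amount correction reconstructs withdrawn analyte", {
  des <- chamber_design()
  ser <- tibble::tibble(compound_id = "x", chamber = 1,
                        time = c(0, 60, 100), conc = c(0, 1, 1))
  corr <- correct_sampling(ser, des, "acceptor")
  # Q = 1 uM x 7 mL + one earlier 0.4 mL aliquot at 1 uM = 7.4 nmol
  expect_equal(corr$cumulative_nmol, c(0, 7, 7.4))
  expect_equal(corr$conc_corrected[3], 7.4 / 7)

  zero <- correct_sampling(dplyr::mutate(ser, conc = 0), des, "acceptor")
  expect_true(all(zero$cumulative_nmol == 0))

  naive <- correct_sampling(ser, des, "acceptor", method = "naive")
  expect_equal(naive$cumulative_nmol, c(0, 7, 7))
})

test_that("corrected acceptor amounts agree with the simulator's removal ledger", {
  sc <- get_scenario("extract")
  truth <- simulate_kinetics(sc$design, sc$compounds, sc$kinetics)
  pue <- truth[truth$compound_id == "puerarin", ]
  true_cum <- pue$acceptor_conc * sc$design$acceptor_volume +
    pue$removed_acceptor
  ser <- tibble::tibble(compound_id = "puerarin", chamber = 1,
                        time = pue$time, conc = pue$acceptor_conc)
  est <- correct_sampling(ser, sc$design, "acceptor")$cumulative_nmol
  expect_equal(est[-1], true_cum[-1], tolerance = 0.005)
})

test_that("the permeability formula converts slope, volume, area and C0 correctly", {
  des <- chamber_design(acceptor_aliquot = 0) # correction is a no-op
  slope_um_min <- 1.8e-5 * 60
  ser <- tibble::tibble(compound_id = "x", chamber = 1,
                        time = des$sampling_times,
                        conc = slope_um_min * des$sampling_times)
  fit <- estimate_papp(ser, des, C0 = 100)
  expect_equal(fit$summary$papp_mean, 1.8e-5 * 7 / (1.26 * 100))
  expect_equal(fit$summary$papp_mean, 1e-6, tolerance = 1e-9)

  flat <- estimate_papp(dplyr::mutate(ser, conc = 0), des, C0 = 100)
  expect_equal(flat$summary$papp_mean, 0)
  expect_error(estimate_papp(ser, des, C0 = 0), "C0")
  few <- dplyr::filter(ser, time %in% c(0, 20, 40))
  expect_error(estimate_papp(few, des, C0 = 100), "fewer than 3")
})

test_that("transport metrics follow the molar-ratio definitions", {
  amounts <- tibble::tibble(
    compound_id = c("puerarin", "daidzein"), chamber = 1,
    nmol_donor_0 = c(700, 700),
    nmol_donor_end = c(690, 10.808),
    nmol_membrane_end = c(3.29, 4.41),
    nmol_acceptor_end = c(1.4, 0)
  )
  expect_equal(q_dep(amounts)$value, c(0.47, 0.63))
  expect_equal(q_perm(amounts)$value, c(0.2, 0))
  expect_equal(transport_index(amounts)$value, c(0.67, 0.63))

  # TI is always the sum of its parts
  set.seed(42)
  rand <- tibble::tibble(
    compound_id = "x", chamber = 1:50,
    nmol_donor_0 = stats::runif(50, 1, 1000),
    nmol_donor_end = stats::runif(50, 0, 1000),
    nmol_membrane_end = stats::runif(50, 0, 100),
    nmol_acceptor_end = stats::runif(50, 0, 100)
  )
  expect_equal(transport_index(rand)$value,
               q_dep(rand)$value + q_perm(rand)$value)
  # extract-referenced deposition is a bounded fraction
  qx <- q_dep_extract(rand)$value
  expect_true(all(qx >= 0 & qx <= 100))

  expect_error(q_dep(dplyr::mutate(amounts, nmol_donor_0 = 0)), "positive")
})

test_that("extract-referenced deposition reproduces worked molar arithmetic", {
  amounts <- tibble::tibble(
    compound_id = c("daidzein", "even", "none"), chamber = 1,
    nmol_donor_0 = 1,
    nmol_donor_end = c(1.544 * 7, 5, 5),
    nmol_membrane_end = c(0.6145, 5, 0),
    nmol_acceptor_end = 0
  )
  v <- q_dep_extract(amounts)$value
  expect_equal(v[1], 100 * 0.6145 / (10.808 + 0.6145), tolerance = 1e-9)
  expect_equal(round(v[1], 2), 5.38)
  expect_equal(v[2], 50)
  expect_equal(v[3], 0)
})

test_that("the metabolite formation index sums all compartments over the precursor", {
  met <- tibble::tibble(compound_id = "agl", chamber = 1:2,
                        nmol_donor_0 = 1e-9,
                        nmol_donor_end = c(10, 0),
                        nmol_membrane_end = c(2, 0),
                        nmol_acceptor_end = 0)
  pre <- tibble::tibble(compound_id = "gly", chamber = 1:2,
                        nmol_donor_0 = 100, nmol_donor_end = 1,
                        nmol_membrane_end = 0, nmol_acceptor_end = 0)
  expect_equal(mfi(met, pre)$value, c(12, 0))
})

test_that("measured amounts and MFI recover the simulated truth on a noise-free run", {
  sc <- get_scenario("pure_daidzin")
  run <- simulate_experiment(sc$design, sc$compounds, sc$kinetics, seed = 9)
  m <- match_targets(run$table, target_list(sc$compounds))
  amounts <- compartment_amounts(run$table, m, sc$design, 3e6)

  truth <- simulate_kinetics(sc$design, sc$compounds, sc$kinetics)
  end <- max(truth$time)
  agl <- truth[truth$compound_id == "daidzein" & truth$time == end, ]
  true_mfi <- 100 * (agl$donor_conc * 7 + agl$membrane_amount +
                       agl$acceptor_conc * 7) / (100 * 7)
  est <- mfi(amounts[amounts$compound_id == "daidzein", ],
             amounts[amounts$compound_id == "daidzin", ])
  expect_equal(mean(est$value), true_mfi, tolerance = 0.01)

  # measured deposited/permeated fractions match the generating truth
  qd <- summarise_metric(q_dep(amounts |>
    dplyr::filter(compound_id == "daidzein") |>
    dplyr::mutate(nmol_donor_0 = 100 * 7)))
  true_qdep <- 100 * agl$membrane_amount / (100 * 7)
  expect_equal(qd$mean, true_qdep, tolerance = 0.01)
})

test_that("the TEER gate excludes any chamber dipping below threshold", {
  teer <- dplyr::bind_rows(
    tibble::tibble(chamber = 1, time_min = 0:100, resistance = 40),
    tibble::tibble(chamber = 2, time_min = 0:100,
                   resistance = c(rep(40, 50), 14, rep(40, 50))),
    tibble::tibble(chamber = 3, time_min = 0:100, resistance = 15)
  )
  gate <- teer_gate(teer)
  expect_equal(gate$viable, c(TRUE, FALSE, TRUE)) # exactly 15 is viable
  expect_equal(gate$min_teer, c(40, 14, 15))
})
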