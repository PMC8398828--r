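# Shared fixtures: all synthetic, built in code.

# single-compound design without aliquot sampling (pure kinetics checks)
design_nosampling <- function(times = c(0, 10, 20, 40, 60, 80, 100)) {
  chamber_design(donor_aliquot = 0, acceptor_aliquot = 0,
                 sampling_times = times, n_replicates = 1)
}

one_compound <- function(id = "cmpA", conc = 100, mz = 417.1181, rt = 2.2) {
  compound_table(id, mz = mz, rt = rt, mw = 416.38,
                 compound_class = "C_glycoside", initial_donor_conc = conc)
}

# expensive calibrated scenarios, memoised across test files
get_scenario <- local({
  cache <- list()
  function(name) {
    if (is.null(cache[[name]])) {
      cache[[name]] <<- switch(
        name,
        extract = scenario_extract(),
        pure_puerarin = scenario_pure_puerarin(end_time = 100),
        pure_puerarin_120 = scenario_pure_puerarin(end_time = 120),
        pure_daidzin = scenario_pure_daidzin()
      )
    }
    cache[[name]]
  }
})

# hand-built table with known heights in every compartment
ratio_fixture <- function(scale = 1) {
  feature_table(tibble::tibble(
    feature_id = c("F1", "F2"),
    mz = c(255.0652, 417.1181), rt = c(6.86, 2.20),
    donor_t0_r1 = scale * c(1.0e6, 2e6),
    donor_t0_r2 = scale * c(1.0e6, 2e6),
    donor_t100_r1 = scale * c(7.74e6, 2e6),
    donor_t100_r2 = scale * c(7.74e6, 2e6),
    acceptor_t100_r1 = scale * c(NA, 1e4),
    acceptor_t100_r2 = scale * c(NA, 1e4),
    membrane_t100_r1 = scale * c(1.34e5, 1e4),
    membrane_t100_r2 = scale * c(1.34e5, 1e4)
  ))
}

fixture_matches <- tibble::tibble(compound_id = c("daidzein", "puerarin"),
                                  feature_id = c("F1", "F2"),
                                  matched = TRUE)

# minimal hand-built ratio row for classifier unit tests
ratio_row <- function(compound_id, kind, mean, status = "ok",
                      num_detected = TRUE, den_detected = TRUE) {
  tibble::tibble(
    compound_id = compound_id, ratio_kind = kind, n = 4L,
    mean = mean, sd = 0, cv = 0, status = status,
    numerator_detected = num_detected, denominator_detected = den_detected,
    replicates = list(rep(mean, 4))
  )
}

# mass-balance audit of a true-state series: per compound, everything now in
# the system plus everything removed or converted out must equal what entered
mass_balance_error <- function(truth, design) {
  total_in <- sum(truth$donor_conc[truth$time == 0]) * design$donor_volume
  by_time <- truth |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(
      balance = sum(.data$donor_conc * design$donor_volume +
                      .data$membrane_amount +
                      .data$acceptor_conc * design$acceptor_volume +
                      .data$removed_donor + .data$removed_acceptor +
                      .data$converted_out - .data$converted_in -
                      .data$added_donor),
      .groups = "drop"
    )
  max(abs(by_time$balance - total_in)) / total_in
}
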