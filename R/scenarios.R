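#' Solve a kinetic rate against a target on the simulated truth
#'
#' Finds, by root bracketing, the rate constant for which `objective(rate)`
#' is zero. Used by the reference scenarios to calibrate generating rates so
#' that a true simulated fraction (deposited, surviving, converted) equals a
#' prescribed value; the analysis pipeline is then expected to recover that
#' value from the measured tables.
#'
#' @param objective Function of one rate returning the signed miss.
#' @param interval Search interval for the rate.
#' @param tol Convergence tolerance.
#' @return The calibrated rate (numeric scalar).
#' @export
calibrate_rate <- function(objective, interval = c(1e-8, 1), tol = 1e-12) {
  stats::uniroot(objective, interval, tol = tol)$root
}

#' Standard chamber designs for extract and pure-standard runs
#'
#' The extract design samples 200 uL donor aliquots at 0, 10, 20, 40, 60, 80
#' and 100 min; the pure-standard design samples 100 uL donor aliquots and
#' runs to `end_time` (120 min by default, with the extra point appended to
#' the schedule). Both replace 400 uL acceptor aliquots with fresh buffer and
#' donor aliquots with stock solution.
#'
#' @param end_time Last sampling time (min) of the pure-standard run.
#' @return A [chamber_design()].
#' @export
design_extract <- function() {
  chamber_design(donor_aliquot = 0.2,
                 sampling_times = c(0, 10, 20, 40, 60, 80, 100))
}

#' @rdname design_extract
#' @export
design_pure <- function(end_time = 120) {
  times <- c(0, 10, 20, 40, 60, 80, 100, 120)
  chamber_design(donor_aliquot = 0.1,
                 sampling_times = times[times <= end_time])
}

isoflavone_panel <- function(which, conc = NULL) {
  all <- compound_table(
    id = c("puerarin", "daidzin", "daidzein", "genistin", "genistein"),
    mz = c(417.1181, 417.1181, 255.0652, 433.1131, 271.0601),
    rt = c(2.20, 3.31, 6.86, 5.13, 7.60),
    mw = c(416.38, 416.38, 254.24, 432.38, 270.24),
    compound_class = c("C_glycoside", "O_glycoside", "aglycone",
                       "O_glycoside", "aglycone"),
    initial_donor_conc = 0
  )
  out <- all[match(which, all$id), , drop = FALSE]
  if (!is.null(conc)) out$initial_donor_conc <- conc
  out
}

#' Calibrated reference scenario: pure puerarin
#'
#' A single-compound pure-standard run in which the generating deposition
#' rate is solved so the true membrane fraction at the end of the run equals
#' `q_dep_true` percent of the initial donor amount, with transmembrane
#' permeability `papp`.
#'
#' @param q_dep_true Target true deposited fraction (percent).
#' @param papp Generating permeability (cm/s).
#' @param c0 Initial donor concentration (uM).
#' @param end_time Last sampling time (min).
#' @return A list `design`, `compounds`, `kinetics`, `c0` ready for
#'   [simulate_experiment()].
#' @export
scenario_pure_puerarin <- function(q_dep_true = 0.47, papp = 9.62e-6,
                                   c0 = 100, end_time = 100) {
  design <- design_pure(end_time)
  compounds <- isoflavone_panel("puerarin", c0)
  truth_frac <- function(k_dep) {
    kin <- kinetic_params("puerarin", papp_true = papp, k_deposit = k_dep)
    ts <- simulate_kinetics(design, compounds, kin, step = 1)
    mem <- ts$membrane_amount[ts$time == end_time]
    100 * mem / (c0 * design$donor_volume) - q_dep_true
  }
  k_dep <- calibrate_rate(truth_frac, c(1e-8, 1e-2))
  list(design = design, compounds = compounds,
       kinetics = kinetic_params("puerarin", papp_true = papp,
                                 k_deposit = k_dep),
       c0 = c(puerarin = c0))
}

#' Calibrated reference scenario: pure daidzin with hydrolysis to daidzein
#'
#' The hydrolysis rate is solved so the true donor daidzin concentration at
#' `end_time` equals `survival` percent of its initial value (under the
#' design's stock-replacement sampling); the daidzein deposition rate is then
#' solved so the true membrane daidzein equals `q_dep_daidzein` percent of
#' the initial donor daidzin amount. Neither compound permeates.
#'
#' @param survival Target true donor survival of daidzin (percent).
#' @param q_dep_daidzein Target true deposited daidzein (percent of initial
#'   daidzin).
#' @param c0 Initial donor daidzin concentration (uM).
#' @param end_time Last sampling time (min).
#' @return As [scenario_pure_puerarin()].
#' @export
scenario_pure_daidzin <- function(survival = 40, q_dep_daidzein = 0.63,
                                  c0 = 100, end_time = 100) {
  design <- design_pure(end_time)
  compounds <- isoflavone_panel(c("daidzin", "daidzein"), c(c0, 0))
  kin_fn <- function(k_hyd, k_dep) {
    kinetic_params(
      c("daidzin", "daidzein"),
      k_hydrolysis = c(k_hyd, 0),
      hydrolysis_product = c("daidzein", NA),
      k_deposit = c(0, k_dep)
    )
  }
  k_hyd <- calibrate_rate(function(k) {
    ts <- simulate_kinetics(design, compounds, kin_fn(k, 0), step = 1)
    100 * ts$donor_conc[ts$compound_id == "daidzin" & ts$time == end_time] /
      c0 - survival
  }, c(1e-6, 1))
  k_dep <- calibrate_rate(function(k) {
    ts <- simulate_kinetics(design, compounds, kin_fn(k_hyd, k), step = 1)
    100 * ts$membrane_amount[ts$compound_id == "daidzein" &
                               ts$time == end_time] /
      (c0 * design$donor_volume) - q_dep_daidzein
  }, c(1e-8, 1))
  list(design = design, compounds = compounds,
       kinetics = kin_fn(k_hyd, k_dep),
       c0 = c(daidzin = c0))
}

#' Calibrated reference scenario: extract run
#'
#' A multi-compound extract run: puerarin permeates with permeability
#' `papp_puerarin`; daidzin and genistin hydrolyse to their aglycones, whose
#' deposition rates are solved so the true membrane/(donor + membrane)
#' fraction of each aglycone at 100 min equals the `q_dep_extract_*` targets,
#' while the hydrolysis rates are solved so the true donor aglycone
#' concentrations at 100 min equal `donor_daidzein` / `donor_genistein`.
#' Because an aglycone's donor pool depends on its own deposition rate, the
#' two one-dimensional solves per pair are alternated to joint convergence.
#'
#' @param papp_puerarin Puerarin generating permeability (cm/s).
#' @param c0_puerarin,c0_daidzin,c0_daidzein,c0_genistin Initial donor
#'   concentrations (uM).
#' @param donor_daidzein,donor_genistein Target true donor aglycone
#'   concentrations at 100 min (uM).
#' @param q_dep_extract_daidzein,q_dep_extract_genistein Target true
#'   membrane/(donor+membrane) fractions (percent).
#' @return As [scenario_pure_puerarin()].
#' @export
scenario_extract <- function(papp_puerarin = 2.61e-6,
                             c0_puerarin = 25.724,
                             c0_daidzin = 5.035,
                             c0_daidzein = 0.138,
                             c0_genistin = 1,
                             donor_daidzein = 1.544,
                             donor_genistein = 0.121,
                             q_dep_extract_daidzein = 5.38,
                             q_dep_extract_genistein = 21.94) {
  design <- design_extract()
  compounds <- isoflavone_panel(
    c("puerarin", "daidzin", "daidzein", "genistin", "genistein"),
    c(c0_puerarin, c0_daidzin, c0_daidzein, c0_genistin, 0)
  )
  end_time <- design$duration
  kin_fn <- function(kh_d, kd_d, kh_g, kd_g) {
    kinetic_params(
      c("puerarin", "daidzin", "daidzein", "genistin", "genistein"),
      papp_true = c(papp_puerarin, 0, 0, 0, 0),
      k_hydrolysis = c(0, kh_d, 0, kh_g, 0),
      hydrolysis_product = c(NA, "daidzein", NA, "genistein", NA),
      k_deposit = c(0, 0, kd_d, 0, kd_g)
    )
  }
  solve_pair <- function(aglycone, donor_target, ratio_target,
                         kin_with) {
    k_hyd <- 0.01; k_dep <- 1e-4
    for (iter in 1:2) {
      k_hyd <- calibrate_rate(function(k) {
        ts <- simulate_kinetics(design, compounds, kin_with(k, k_dep), step = 1)
        ts$donor_conc[ts$compound_id == aglycone & ts$time == end_time] -
          donor_target
      }, c(1e-6, 1))
      k_dep <- calibrate_rate(function(k) {
        ts <- simulate_kinetics(design, compounds, kin_with(k_hyd, k), step = 1)
        don <- ts$donor_conc[ts$compound_id == aglycone &
                               ts$time == end_time] * design$donor_volume
        mem <- ts$membrane_amount[ts$compound_id == aglycone &
                                    ts$time == end_time]
        100 * mem / (don + mem) - ratio_target
      }, c(1e-8, 1))
    }
    c(k_hyd, k_dep)
  }
  kd <- solve_pair("daidzein", donor_daidzein, q_dep_extract_daidzein,
                   function(kh, kdep) kin_fn(kh, kdep, 0.01, 1e-4))
  kg <- solve_pair("genistein", donor_genistein, q_dep_extract_genistein,
                   function(kh, kdep) kin_fn(kd[1], kd[2], kh, kdep))
  list(design = design, compounds = compounds,
       kinetics = kin_fn(kd[1], kd[2], kg[1], kg[2]),
       c0 = c(puerarin = c0_puerarin, daidzin = c0_daidzin,
              daidzein = c0_daidzein, genistin = c0_genistin,
              genistein = 0))
}
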