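#' Simulate the true kinetics of an Ussing-chamber run
#'
#' Solves, per compound, the deterministic three-pool system
#' donor solution -> membrane tissue -> acceptor solution with first-order
#' transmembrane permeation (`papp_true`), tissue deposition and release,
#' and donor-compartment hydrolysis/hydroxylation feeding product compounds.
#' Aliquot withdrawal at each sampling time is applied as an instantaneous
#' event: the acceptor aliquot is replaced by fresh buffer (dilution) and the
#' donor aliquot by either stock solution (re-injecting the initial
#' concentration) or fresh buffer, per the design.
#'
#' Integration is fixed-step classical 4th-order Runge-Kutta (default 0.1 min)
#' with exact stops at sampling times; the dynamics are non-stiff and the
#' scheme is fully reproducible. Internally concentrations are uM, amounts
#' nmol, volumes mL and time min; `papp_true` (cm/s) is converted once at the
#' rate-constant boundary (1 min = 60 s, 1 mL = 1 cm3).
#'
#' The returned series is the state an aliquot would measure, i.e. recorded at
#' each sampling time *before* the withdrawal/replacement event. Cumulative
#' bookkeeping columns (`removed_donor`, `removed_acceptor`, `added_donor`,
#' `converted_out`, `converted_in`, all nmol) make the mass balance auditable:
#' at every time, `donor + membrane + acceptor + removed - added - net
#' conversion` equals the initial donor amount.
#'
#' @param design A [chamber_design()].
#' @param compounds A [compound_table()].
#' @param kinetics A [kinetic_params()] table; compounds absent from it get
#'   all-zero rates.
#' @param step Integration step (min).
#'
#' @return A tibble (class `true_state`) with one row per compound and
#'   sampling time: `compound_id`, `time`, `donor_conc` (uM),
#'   `membrane_amount` (nmol), `acceptor_conc` (uM), and the cumulative
#'   bookkeeping columns.
#' @export
simulate_kinetics <- function(design, compounds, kinetics, step = 0.1) {
  stopifnot(inherits(design, "chamber_design"), step > 0)
  kin <- align_kinetics(compounds, kinetics)
  n <- nrow(kin)
  ids <- kin$compound_id

  prod_idx <- function(col) match(kin[[col]], ids)
  hyd_to <- prod_idx("hydrolysis_product")
  oh_to <- prod_idx("hydroxylation_product")
  bad <- (!is.na(kin$hydrolysis_product) & is.na(hyd_to)) |
    (!is.na(kin$hydroxylation_product) & is.na(oh_to))
  if (any(bad)) {
    stop("unknown product id for compound(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }

  vd <- design$donor_volume
  va <- design$acceptor_volume
  # cm/s -> 1/min first-order rate constants for each receiving volume
  perm_d <- kin$papp_true * 60 * design$exposed_area / vd
  perm_a <- kin$papp_true * 60 * design$exposed_area / va
  loss <- perm_d + kin$k_deposit + kin$k_hydrolysis + kin$k_hydroxylation

  # state layout: [C_D, M, C_A, conv_out, conv_in] per compound
  deriv <- function(s) {
    cd <- s[, 1]; m <- s[, 2]
    gain_d <- numeric(n)
    hyd_flux <- kin$k_hydrolysis * cd
    oh_flux <- kin$k_hydroxylation * cd
    ok <- !is.na(hyd_to)
    if (any(ok)) gain_d[hyd_to[ok]] <- gain_d[hyd_to[ok]] + hyd_flux[ok]
    ok <- !is.na(oh_to)
    if (any(ok)) gain_d[oh_to[ok]] <- gain_d[oh_to[ok]] + oh_flux[ok]
    cbind(
      -loss * cd + gain_d,
      kin$k_deposit * cd * vd - kin$k_release * m,
      perm_a * cd + kin$k_release * m / va,
      (kin$k_hydrolysis + kin$k_hydroxylation) * cd * vd,
      gain_d * vd
    )
  }
  rk4_step <- function(s, h) {
    k1 <- deriv(s)
    k2 <- deriv(s + h / 2 * k1)
    k3 <- deriv(s + h / 2 * k2)
    k4 <- deriv(s + h * k3)
    s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }

  state <- cbind(kin$initial_donor_conc, 0, 0, 0, 0)
  removed_d <- removed_a <- added_d <- numeric(n)
  times <- design$sampling_times
  records <- vector("list", length(times))

  record <- function(i) {
    records[[i]] <<- tibble::tibble(
      compound_id = ids, time = times[i],
      donor_conc = state[, 1], membrane_amount = state[, 2],
      acceptor_conc = state[, 3],
      removed_donor = removed_d, removed_acceptor = removed_a,
      added_donor = added_d,
      converted_out = state[, 4], converted_in = state[, 5]
    )
  }
  sample_event <- function() {
    removed_d <<- removed_d + state[, 1] * design$donor_aliquot
    removed_a <<- removed_a + state[, 3] * design$acceptor_aliquot
    if (design$donor_replacement == "stock_solution") {
      added_d <<- added_d + kin$initial_donor_conc * design$donor_aliquot
      state[, 1] <<- (state[, 1] * (vd - design$donor_aliquot) +
                        kin$initial_donor_conc * design$donor_aliquot) / vd
    } else {
      state[, 1] <<- state[, 1] * (vd - design$donor_aliquot) / vd
    }
    state[, 3] <<- state[, 3] * (va - design$acceptor_aliquot) / va
  }

  record(1)
  sample_event()
  for (i in seq_along(times)[-1]) {
    span <- times[i] - times[i - 1]
    nsteps <- max(1L, as.integer(round(span / step)))
    h <- span / nsteps
    for (j in seq_len(nsteps)) state <- rk4_step(state, h)
    if (any(state[, 1:3] < -1e-9)) {
      stop("negative state encountered; integration step too coarse",
           call. = FALSE)
    }
    state[, 1:3][state[, 1:3] < 0] <- 0
    record(i)
    if (i < length(times)) sample_event()
  }

  out <- dplyr::bind_rows(records)
  out <- dplyr::arrange(out, .data$compound_id, .data$time)
  attr(out, "design") <- design
  attr(out, "compounds") <- compounds
  class(out) <- c("true_state", class(out))
  out
}

align_kinetics <- function(compounds, kinetics) {
  kin <- dplyr::left_join(
    dplyr::select(compounds, "id", "initial_donor_conc"),
    kinetics,
    by = c(id = "compound_id")
  )
  kin <- dplyr::rename(kin, compound_id = "id")
  num <- c("papp_true", "k_deposit", "k_release", "k_hydrolysis",
           "k_hydroxylation")
  for (col in num) {
    if (!col %in% names(kin)) kin[[col]] <- 0
    kin[[col]][is.na(kin[[col]])] <- 0
  }
  for (col in c("hydrolysis_product", "hydroxylation_product")) {
    if (!col %in% names(kin)) kin[[col]] <- NA_character_
  }
  kin
}

#' Turn a true-state series into a measured LC-MS feature table
#'
#' Emits one sample column per compartment, sampling time and replicate
#' chamber, plus membrane-extract samples at the end time, triplicate stock
#' samples and a blank-membrane sample. Peak height is
#' `response_factor x concentration x lognormal(mean 1, cv noise_cv)`;
#' heights below the censor floor are absent (`NA`). Membrane samples report
#' the tissue amount divided by the nominal extract volume. The same seed
#' always yields the identical table.
#'
#' @param true_state A `true_state` series from [simulate_kinetics()].
#' @param design The matching [chamber_design()].
#' @param model A [measurement_model()].
#' @param seed Integer seed for the measurement noise.
#' @param n_stock_replicates Analytical replicates of the stock solution.
#' @param endogenous Optional named vector (compound id -> peak height) of
#'   interfering heights injected into blank-membrane and membrane samples,
#'   to exercise blank subtraction. Default none.
#'
#' @return A [feature_table] whose features are the simulated compounds.
#' @export
apply_measurement <- function(true_state, design, model, seed = 1L,
                              n_stock_replicates = 3L, endogenous = NULL) {
  stopifnot(inherits(true_state, "true_state"),
            inherits(model, "measurement_model"))
  compounds <- attr(true_state, "compounds")
  ids <- compounds$id
  rf <- response_factor_for(model, ids)
  end_time <- max(true_state$time)

  wide <- function(col) {
    m <- tidyr::pivot_wider(
      dplyr::select(true_state, "compound_id", "time",
                    value = dplyr::all_of(col)),
      names_from = "time", values_from = "value"
    )
    m <- m[match(ids, m$compound_id), , drop = FALSE]
    as.matrix(m[, -1, drop = FALSE])
  }
  donor <- wide("donor_conc")
  acceptor <- wide("acceptor_conc")
  membrane_end <- wide("membrane_amount")[, as.character(end_time)]
  times <- sort(unique(true_state$time))

  endo_height <- stats::setNames(numeric(length(ids)), ids)
  if (!is.null(endogenous)) {
    endo_height[names(endogenous)] <- endogenous
  }

  cols <- list()
  truth <- list() # true concentration per sample column (uM)
  add_sample <- function(name, conc) {
    truth[[name]] <<- as.numeric(conc)
  }
  for (r in seq_len(n_stock_replicates)) {
    add_sample(sprintf("stock_t0_r%d", r), compounds$initial_donor_conc)
  }
  for (r in seq_len(design$n_replicates)) {
    for (ti in seq_along(times)) {
      add_sample(sprintf("donor_t%g_r%d", times[ti], r), donor[, ti])
      add_sample(sprintf("acceptor_t%g_r%d", times[ti], r), acceptor[, ti])
    }
    add_sample(sprintf("membrane_t%g_r%d", end_time, r),
               membrane_end / design$extract_volume)
  }
  add_sample(sprintf("blank_membrane_t%g_r1", end_time),
             numeric(length(ids)))

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)

  sdlog <- sqrt(log(1 + model$noise_cv^2))
  for (name in names(truth)) {
    conc <- truth[[name]]
    height <- rf * conc
    if (model$noise_cv > 0) {
      height <- height * stats::rlnorm(length(height),
                                       meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    if (grepl("membrane", name)) {
      height <- height + endo_height
    }
    height[height < model$lod_height] <- NA_real_
    cols[[name]] <- unname(height)
  }

  tab <- tibble::tibble(
    feature_id = sprintf("FT%03d", seq_along(ids)),
    mz = compounds$mz,
    rt = compounds$rt
  )
  for (name in names(cols)) tab[[name]] <- cols[[name]]
  new_feature_table(tab)
}

#' Simulate a TEER viability trace
#'
#' Transepithelial electrical resistance is recorded once per minute as an
#' exponential decay from a baseline plus gaussian noise, floored at zero.
#'
#' @param design A [chamber_design()]; one trace per replicate chamber.
#' @param baseline Starting resistance (Ohm cm2).
#' @param decay_rate First-order decay rate (1/min).
#' @param noise_sd Gaussian noise SD (Ohm cm2).
#' @param seed Integer seed.
#'
#' @return A tibble `chamber`, `time_min`, `resistance`.
#' @export
simulate_teer <- function(design, baseline = 40, decay_rate = 0,
                          noise_sd = 0, seed = 1L) {
  stopifnot(inherits(design, "chamber_design"), all(baseline > 0),
            all(decay_rate >= 0), noise_sd >= 0)
  baseline <- rep_len(baseline, design$n_replicates)
  decay_rate <- rep_len(decay_rate, design$n_replicates)
  times <- seq(0, design$duration, by = 1)
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  purrr::map_dfr(seq_len(design$n_replicates), function(ch) {
    r <- baseline[ch] * exp(-decay_rate[ch] * times)
    if (noise_sd > 0) r <- r + stats::rnorm(length(times), 0, noise_sd)
    tibble::tibble(chamber = ch, time_min = times,
                   resistance = pmax(r, 0))
  })
}

#' Simulate a complete measured experiment
#'
#' Convenience wrapper chaining [simulate_kinetics()], [apply_measurement()]
#' and [simulate_teer()].
#'
#' @inheritParams simulate_kinetics
#' @inheritParams apply_measurement
#' @param teer_baseline,teer_decay,teer_noise_sd TEER trace parameters.
#' @return A list with `truth` (true-state series), `table` (feature table)
#'   and `teer` (TEER traces).
#' @export
simulate_experiment <- function(design, compounds, kinetics,
                                model = measurement_model(), seed = 1L,
                                teer_baseline = 40, teer_decay = 0,
                                teer_noise_sd = 0, step = 0.1) {
  truth <- simulate_kinetics(design, compounds, kinetics, step = step)
  list(
    truth = truth,
    table = apply_measurement(truth, design, model, seed = seed),
    teer = simulate_teer(design, teer_baseline, teer_decay,
                         teer_noise_sd, seed = seed + 1L)
  )
}
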