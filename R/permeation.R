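#' Extract a concentration series from a measured feature table
#'
#' Converts matched peak heights into concentrations (uM) with a known
#' proportional response factor (height units per uM). Censored (absent)
#' heights become zero concentration, the convention used for amount sums.
#' For quantification against a fitted external calibration use [quantify()]
#' on the heights instead and convert nM to uM at this boundary.
#'
#' @param table A [feature_table].
#' @param matches Output of [match_targets()].
#' @param response_factor Height units per uM; single value or named vector
#'   keyed by compound id.
#' @param compartments Which compartments to extract.
#' @return A tibble `compound_id`, `compartment`, `chamber`, `time`, `conc`.
#' @export
concentration_series <- function(table, matches, response_factor,
                                 compartments = c("donor", "acceptor",
                                                  "membrane")) {
  stopifnot(inherits(table, "feature_table"))
  info <- sample_info(table)
  info <- info[info$compartment %in% compartments, , drop = FALSE]
  rf <- if (is.null(names(response_factor))) {
    stats::setNames(rep(response_factor[[1]], nrow(matches)),
                    matches$compound_id)
  } else response_factor
  purrr::map_dfr(seq_len(nrow(matches)), function(i) {
    fid <- matches$feature_id[i]
    cid <- matches$compound_id[i]
    if (is.na(fid)) return(NULL)
    h <- heights_for(table, fid, info$sample_id)
    tibble::tibble(
      compound_id = cid,
      compartment = info$compartment,
      chamber = info$chamber,
      time = info$time,
      conc = ifelse(is.na(h), 0, h) / rf[[cid]]
    )
  })
}

#' Correct acceptor concentrations for aliquot withdrawal
#'
#' Each sampling event removes an aliquot (and its analyte) from the
#' compartment and replaces it with fresh buffer, so later measured
#' concentrations understate the cumulative amount transported. The
#' cumulative-amount correction reconstructs, at sampling time `t_n`,
#' `Q_n = c_n V + sum_{i<n} c_i v` (nmol), i.e. what is in the compartment
#' plus everything previously carried away in aliquots, and reports the
#' equivalent concentration `Q_n / V` for slope fitting. `method = "naive"`
#' skips the correction for sensitivity comparison.
#'
#' @param series A concentration series (tibble with `compound_id`,
#'   `chamber`, `time`, `conc`), typically the acceptor rows of
#'   [concentration_series()].
#' @param design The [chamber_design()]; supplies the compartment volume and
#'   aliquot volume.
#' @param compartment `"acceptor"` (default) or `"donor"` — selects which
#'   volume/aliquot pair applies.
#' @param method `"cumulative"` or `"naive"`.
#' @return The series with added columns `cumulative_nmol` and
#'   `conc_corrected` (uM).
#' @export
correct_sampling <- function(series, design,
                             compartment = c("acceptor", "donor"),
                             method = c("cumulative", "naive")) {
  compartment <- match.arg(compartment)
  method <- match.arg(method)
  volume <- switch(compartment, acceptor = design$acceptor_volume,
                   donor = design$donor_volume)
  aliquot <- switch(compartment, acceptor = design$acceptor_aliquot,
                    donor = design$donor_aliquot)
  if (aliquot >= volume) stop("aliquot >= compartment volume", call. = FALSE)
  series |>
    dplyr::group_by(.data$compound_id, .data$chamber) |>
    dplyr::arrange(.data$time, .by_group = TRUE) |>
    dplyr::mutate(
      cumulative_nmol = .data$conc * volume +
        if (method == "cumulative") {
          dplyr::lag(cumsum(.data$conc * aliquot), default = 0)
        } else 0,
      conc_corrected = .data$cumulative_nmol / volume
    ) |>
    dplyr::ungroup()
}

#' Estimate the apparent permeability coefficient
#'
#' Fits, per chamber, a least-squares line to the sampling-corrected acceptor
#' concentration over the fitting window (default 20-80 min, endpoints
#' included, intercept free so any lag time is absorbed) and converts the
#' slope to `P_app = (dc/dt) V / (A C0)` in cm/s, with `dc/dt` in uM/s, `V`
#' the donor-compartment volume (cm3), `A` the exposed area (cm2) and `C0`
#' the measured initial donor concentration (uM).
#'
#' @param series Acceptor concentration series (`compound_id`, `chamber`,
#'   `time`, `conc` in uM).
#' @param design The [chamber_design()].
#' @param C0 Initial donor concentration (uM); single value or named vector
#'   by compound id.
#' @param window Fitting window (min), endpoints included.
#' @param correction Sampling-correction method passed to
#'   [correct_sampling()].
#' @param viable Optional viability report from [teer_gate()]; non-viable
#'   chambers are excluded.
#' @return An object of class `papp_fit`: per-chamber slopes and
#'   permeabilities plus their mean and SD per compound. Access tidy output
#'   with `tidy()` (per chamber) or `glance()` (per compound).
#' @export
estimate_papp <- function(series, design, C0, window = c(20, 80),
                          correction = c("cumulative", "naive"),
                          viable = NULL) {
  correction <- match.arg(correction)
  stopifnot(all(window %in% design$sampling_times))
  if (!is.null(viable)) {
    keep <- viable$chamber[viable$viable]
    series <- dplyr::filter(series, .data$chamber %in% keep)
  }
  c0_for <- function(cid) {
    v <- if (is.null(names(C0))) C0[[1]] else C0[[cid]]
    if (is.na(v) || v <= 0) stop("C0 must be positive for compound ", cid,
                                 call. = FALSE)
    v
  }
  corrected <- correct_sampling(series, design, "acceptor", correction)
  fits <- corrected |>
    dplyr::filter(.data$time >= window[1], .data$time <= window[2]) |>
    dplyr::group_by(.data$compound_id, .data$chamber) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) stop("fewer than 3 points in fitting window",
                            call. = FALSE)
      fit <- stats::lm(conc_corrected ~ time, data = d)
      slope_um_s <- stats::coef(fit)[["time"]] / 60
      tibble::tibble(
        dcdt = slope_um_s,
        papp = slope_um_s * design$donor_volume /
          (design$exposed_area * c0_for(key$compound_id)),
        r2 = r_squared(fit),
        n_points = nrow(d)
      )
    }) |>
    dplyr::ungroup()
  summary <- fits |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(
      n_chambers = dplyr::n(),
      papp_mean = mean(.data$papp),
      papp_sd = if (dplyr::n() > 1) stats::sd(.data$papp) else NA_real_,
      .groups = "drop"
    )
  structure(
    list(per_chamber = fits, summary = summary,
         window = window, correction = correction),
    class = "papp_fit"
  )
}

#' @export
print.papp_fit <- function(x, ...) {
  cat(sprintf("<papp_fit> window %g-%g min, %s correction\n",
              x$window[1], x$window[2], x$correction))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %s: P_app = %.3g +/- %.2g cm/s (n = %d)\n",
                x$summary$compound_id[i], x$summary$papp_mean[i],
                x$summary$papp_sd[i], x$summary$n_chambers[i]))
  }
  invisible(x)
}

#' @method tidy papp_fit
#' @export
tidy.papp_fit <- function(x, ...) x$per_chamber

#' @method glance papp_fit
#' @export
glance.papp_fit <- function(x, ...) x$summary

#' Molar amounts per compartment from a measured table
#'
#' Converts matched heights into the per-chamber molar bookkeeping the
#' transport metrics consume: initial donor amount (donor time-0
#' concentration, or the stock mean when absent, times the donor volume),
#' final donor amount, membrane amount (extract concentration times the
#' nominal extract volume) and the sampling-corrected cumulative acceptor
#' amount at the end of the run. Censored heights count as zero.
#'
#' @inheritParams concentration_series
#' @param design The [chamber_design()].
#' @param correction Acceptor sampling-correction method.
#' @return A tibble `compound_id`, `chamber`, `nmol_donor_0`,
#'   `nmol_donor_end`, `nmol_membrane_end`, `nmol_acceptor_end`.
#' @export
compartment_amounts <- function(table, matches, design, response_factor,
                                correction = c("cumulative", "naive")) {
  correction <- match.arg(correction)
  series <- concentration_series(table, matches, response_factor,
                                 compartments = c("donor", "acceptor",
                                                  "membrane"))
  if (nrow(series) == 0) return(tibble::tibble())
  end_time <- max(series$time)
  info <- sample_info(table)

  # stock-mean fallback concentration per compound, for runs without donor t0
  stock_cols <- info$sample_id[info$compartment == "stock"]
  rf <- if (is.null(names(response_factor))) {
    stats::setNames(rep(response_factor[[1]], nrow(matches)),
                    matches$compound_id)
  } else response_factor
  stock_conc <- purrr::map_dbl(seq_len(nrow(matches)), function(i) {
    h <- heights_for(table, matches$feature_id[i], stock_cols)
    if (length(h) == 0 || all(is.na(h))) return(0)
    mean(ifelse(is.na(h), 0, h)) / rf[[matches$compound_id[i]]]
  })
  names(stock_conc) <- matches$compound_id

  acceptor <- series |>
    dplyr::filter(.data$compartment == "acceptor") |>
    correct_sampling(design, "acceptor", correction) |>
    dplyr::filter(.data$time == end_time) |>
    dplyr::select("compound_id", "chamber",
                  nmol_acceptor_end = "cumulative_nmol")
  donor <- series |>
    dplyr::filter(.data$compartment == "donor") |>
    tidyr::pivot_wider(names_from = "time", values_from = "conc",
                       names_prefix = "t")
  donor0 <- if ("t0" %in% names(donor)) donor$t0 else
    stock_conc[donor$compound_id]
  out <- tibble::tibble(
    compound_id = donor$compound_id,
    chamber = donor$chamber,
    nmol_donor_0 = donor0 * design$donor_volume,
    nmol_donor_end = donor[[paste0("t", end_time)]] * design$donor_volume
  )
  membrane <- series |>
    dplyr::filter(.data$compartment == "membrane") |>
    dplyr::mutate(nmol_membrane_end = .data$conc * design$extract_volume) |>
    dplyr::select("compound_id", "chamber", "nmol_membrane_end")
  out |>
    dplyr::left_join(membrane, by = c("compound_id", "chamber")) |>
    dplyr::left_join(acceptor, by = c("compound_id", "chamber")) |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("nmol"),
                                ~ ifelse(is.na(.x), 0, .x)))
}

#' Transport metrics: deposited, permeated and transport index
#'
#' `q_dep()` is the percent of the initial donor amount found in the membrane
#' at the end of the run, `q_perm()` the percent transported to the acceptor,
#' and `transport_index()` their sum. All are computed per chamber from a
#' [compartment_amounts()] table.
#'
#' @param amounts A [compartment_amounts()] tibble (or any tibble with the
#'   same `nmol_*` columns).
#' @return A tibble `compound_id`, `chamber`, `value` (percent).
#' @export
q_dep <- function(amounts) {
  check_donor0(amounts)
  metric_tbl(amounts, 100 * amounts$nmol_membrane_end / amounts$nmol_donor_0)
}

#' @rdname q_dep
#' @export
q_perm <- function(amounts) {
  check_donor0(amounts)
  metric_tbl(amounts, 100 * amounts$nmol_acceptor_end / amounts$nmol_donor_0)
}

#' @rdname q_dep
#' @export
transport_index <- function(amounts) {
  d <- q_dep(amounts)
  p <- q_perm(amounts)
  metric_tbl(amounts, d$value + p$value)
}

#' Deposition ratio referenced to the final donor pool
#'
#' For extracts, a metabolite in the membrane can descend from several
#' precursors, so its deposition cannot be referenced to any single initial
#' amount. This ratio instead reports the membrane amount over the sum of
#' final donor and membrane amounts,
#' `100 x membrane / (donor_end + membrane)`, which is bounded in \[0, 100\].
#'
#' @inheritParams q_dep
#' @export
q_dep_extract <- function(amounts) {
  denom <- amounts$nmol_donor_end + amounts$nmol_membrane_end
  if (any(denom <= 0)) {
    stop("donor_end + membrane_end must be positive", call. = FALSE)
  }
  metric_tbl(amounts, 100 * amounts$nmol_membrane_end / denom)
}

#' Metabolite formation index
#'
#' Total metabolite recovered across donor, membrane and acceptor at the end
#' of the run, as a percent of the precursor's initial donor amount; chambers
#' are paired between the two tables.
#'
#' @param metabolite_amounts [compartment_amounts()] rows for the metabolite.
#' @param precursor_amounts [compartment_amounts()] rows for the precursor.
#' @return A tibble `compound_id` (metabolite), `chamber`, `value` (percent).
#' @export
mfi <- function(metabolite_amounts, precursor_amounts) {
  check_donor0(precursor_amounts)
  pre <- dplyr::select(precursor_amounts, "chamber",
                       precursor_donor_0 = "nmol_donor_0")
  joined <- dplyr::inner_join(metabolite_amounts, pre, by = "chamber")
  metric_tbl(joined, 100 * (joined$nmol_donor_end + joined$nmol_membrane_end +
                              joined$nmol_acceptor_end) /
               joined$precursor_donor_0)
}

check_donor0 <- function(amounts) {
  if (any(amounts$nmol_donor_0 <= 0)) {
    stop("initial donor amount must be positive", call. = FALSE)
  }
}

metric_tbl <- function(amounts, value) {
  tibble::tibble(compound_id = amounts$compound_id,
                 chamber = amounts$chamber, value = value)
}

#' Summarise a per-chamber metric as mean, SD and CV
#'
#' @param metric A per-chamber metric tibble (`compound_id`, `chamber`,
#'   `value`), as returned by [q_dep()] and friends.
#' @return A tibble `compound_id`, `n`, `mean`, `sd`, `cv`.
#' @export
summarise_metric <- function(metric) {
  metric |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else NA_real_,
      cv = if (dplyr::n() > 1 && mean(.data$value) > 0) {
        stats::sd(.data$value) / mean(.data$value) * 100
      } else NA_real_,
      .groups = "drop"
    )
}

#' Gate chambers on TEER viability
#'
#' A tissue whose transepithelial electrical resistance dips below the
#' threshold at any point during the run is considered non-viable or
#' non-intact and all its samples are excluded from analysis. A minimum of
#' exactly the threshold still counts as viable (the rule is "below").
#'
#' @param teer TEER traces (`chamber`, `time_min`, `resistance`), e.g. from
#'   [simulate_teer()].
#' @param threshold Viability threshold (Ohm cm2).
#' @return A tibble `chamber`, `min_teer`, `viable`.
#' @export
teer_gate <- function(teer, threshold = 15) {
  teer |>
    dplyr::group_by(.data$chamber) |>
    dplyr::summarise(min_teer = min(.data$resistance), .groups = "drop") |>
    dplyr::mutate(viable = .data$min_teer >= threshold)
}
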