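#' Classify the fate of each monitored compound
#'
#' Reproduces the interpretive logic used to read a compartment-ratio table:
#' blank-membrane interference excludes a compound outright; detection in the
#' acceptor makes it a `permeant`; a compound absent at time 0 but present in
#' the donor at the end of the run is an `intestinal_metabolite`; a
#' donor(end)/donor(0) ratio inside the stability band means
#' `stable_in_donor`; below the band, `depleted_precursor` (e.g. an
#' O-glycoside hydrolysed by brush-border/cytosolic beta-glucosidases); above
#' the band, `hydroxylation_product` when the compound sits one oxygen
#' (15.9949 Da, within 5 ppm) above another monitored compound, otherwise
#' `intestinal_metabolite`. A membrane ratio above `membrane_min` with a
#' stable donor appends `membrane_retained` as secondary evidence.
#'
#' @param ratios Output of [compute_ratios()] covering at least
#'   `DON100_DON0`; membrane kinds enrich the evidence.
#' @param permeant Output of [permeant_call()].
#' @param interference Optional output of [check_blank_interference()].
#' @param targets Optional [compound_table()] / [target_list()] used for the
#'   +O (hydroxylation) mass relationship.
#' @param stability_band Donor(end)/donor(0) percent band treated as stable.
#' @param membrane_min Minimum membrane ratio (percent) counted as retention
#'   evidence.
#' @return A tibble `compound_id`, `label`, `evidence` (list-column of
#'   tibbles `ratio_kind`, `value`, `threshold`). Classification is a pure
#'   function of its inputs.
#' @export
classify_fate <- function(ratios, permeant, interference = NULL,
                          targets = NULL,
                          stability_band = c(80, 120),
                          membrane_min = 0.1) {
  stopifnot(length(stability_band) == 2, stability_band[1] < stability_band[2])
  ids <- sort(unique(ratios$compound_id))
  purrr::map_dfr(ids, function(cid) {
    classify_one(cid, ratios, permeant, interference, targets,
                 stability_band, membrane_min)
  })
}

classify_one <- function(cid, ratios, permeant, interference, targets,
                         band, membrane_min) {
  r <- function(kind) {
    row <- ratios[ratios$compound_id == cid & ratios$ratio_kind == kind, ]
    if (nrow(row) == 0) NULL else row
  }
  evidence <- list()
  add_ev <- function(kind, value, threshold) {
    evidence[[length(evidence) + 1L]] <<- tibble::tibble(
      ratio_kind = kind, value = value, threshold = threshold)
  }
  out <- function(label) {
    tibble::tibble(
      compound_id = cid, label = label,
      evidence = list(if (length(evidence)) dplyr::bind_rows(evidence)
                      else tibble::tibble(ratio_kind = character(),
                                          value = numeric(),
                                          threshold = numeric()))
    )
  }
  membrane_evidence <- function() {
    for (kind in c("MEM_DON100", "MEM_DON0")) {
      row <- r(kind)
      if (!is.null(row) && row$status == "ok" && !is.na(row$mean) &&
          row$mean >= membrane_min) {
        add_ev(kind, row$mean, membrane_min)
        return(invisible(TRUE))
      }
    }
    invisible(FALSE)
  }

  if (!is.null(interference)) {
    flag <- interference$interference[interference$compound_id == cid]
    if (length(flag) && isTRUE(flag[1])) {
      add_ev("MEM_DON100", NA_real_, NA_real_)
      return(out("interference_excluded"))
    }
  }
  don <- r("DON100_DON0")
  if (is.null(don)) stop("DON100_DON0 ratio required for compound ", cid,
                         call. = FALSE)
  if (!isTRUE(don$numerator_detected) && !isTRUE(don$denominator_detected)) {
    return(out("not_detected"))
  }

  perm <- permeant[permeant$compound_id == cid, ]
  if (nrow(perm) && isTRUE(perm$permeant[1])) {
    add_ev("ACC100_DON0", perm$acc_don0_ratio[1], attr(permeant, "threshold") %||% 0.1)
    membrane_evidence()
    return(out("permeant"))
  }
  if (!isTRUE(don$denominator_detected) && isTRUE(don$numerator_detected)) {
    add_ev("DON100_DON0", NA_real_, NA_real_)
    membrane_evidence()
    return(out("intestinal_metabolite"))
  }
  if (!isTRUE(don$numerator_detected)) {
    # present at t0, gone at end: fully consumed precursor
    add_ev("DON100_DON0", 0, band[1])
    return(out("depleted_precursor"))
  }
  value <- don$mean
  if (value >= band[1] && value <= band[2]) {
    add_ev("DON100_DON0", value, band[1])
    if (membrane_evidence()) {
      # stable in the donor yet measurably present in tissue
      return(out("stable_in_donor"))
    }
    return(out("stable_in_donor"))
  }
  if (value < band[1]) {
    add_ev("DON100_DON0", value, band[1])
    return(out("depleted_precursor"))
  }
  add_ev("DON100_DON0", value, band[2])
  membrane_evidence()
  if (!is.null(targets) && is_plus_oxygen(cid, targets)) {
    return(out("hydroxylation_product"))
  }
  out("intestinal_metabolite")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# TRUE when the compound's m/z sits one oxygen above another monitored
# compound (monoisotopic +O = 15.9949 Da, matched within 5 ppm)
is_plus_oxygen <- function(cid, targets, ppm_tol = 5) {
  mz <- targets$mz[targets$id == cid]
  if (length(mz) == 0) return(FALSE)
  others <- targets$mz[targets$id != cid]
  any(abs((mz - others) - 15.9949) <= ppm_tol * 1e-6 * mz)
}

#' Assemble the run report
#'
#' Collects every per-compound output into one long-format table
#' (compound x metric) and a human-readable summary naming permeants,
#' intestinal metabolites and excluded chambers. Ordering is deterministic
#' (by compound id, then metric).
#'
#' @param ratios Output of [compute_ratios()].
#' @param fate Output of [classify_fate()].
#' @param viability Optional [teer_gate()] output.
#' @param papp Optional [estimate_papp()] fit.
#' @param metrics Optional named list of summarised metric tibbles from
#'   [summarise_metric()] (e.g. `list(q_dep = ..., ti = ...)`).
#' @return A list with `table` (long tibble `compound_id`, `metric`, `mean`,
#'   `sd`, `cv`, `status`) and `summary` (character lines).
#' @export
render_report <- function(ratios, fate, viability = NULL, papp = NULL,
                          metrics = NULL) {
  ids <- sort(unique(ratios$compound_id))
  if (!setequal(ids, fate$compound_id)) {
    stop("compound ids differ between ratios and fate tables", call. = FALSE)
  }
  long <- ratios |>
    dplyr::transmute(
      compound_id = .data$compound_id, metric = .data$ratio_kind,
      mean = .data$mean, sd = .data$sd, cv = .data$cv,
      status = .data$status
    )
  if (!is.null(papp)) {
    long <- dplyr::bind_rows(long, papp$summary |>
      dplyr::transmute(compound_id = .data$compound_id, metric = "papp",
                       mean = .data$papp_mean, sd = .data$papp_sd,
                       cv = NA_real_, status = "ok"))
  }
  for (nm in names(metrics)) {
    long <- dplyr::bind_rows(long, metrics[[nm]] |>
      dplyr::transmute(compound_id = .data$compound_id, metric = nm,
                       mean = .data$mean, sd = .data$sd, cv = .data$cv,
                       status = "ok"))
  }
  long <- dplyr::bind_rows(long, fate |>
    dplyr::transmute(compound_id = .data$compound_id, metric = "fate",
                     mean = NA_real_, sd = NA_real_, cv = NA_real_,
                     status = .data$label))
  long <- dplyr::arrange(long, .data$compound_id, .data$metric)

  permeants <- fate$compound_id[fate$label == "permeant"]
  metabolites <- fate$compound_id[fate$label %in%
                                    c("intestinal_metabolite",
                                      "hydroxylation_product")]
  lines <- c(
    sprintf("Compounds monitored: %d", length(ids)),
    sprintf("Permeants: %s",
            if (length(permeants)) paste(sort(permeants), collapse = ", ")
            else "none"),
    sprintf("Intestinal metabolites: %s",
            if (length(metabolites)) paste(sort(metabolites), collapse = ", ")
            else "none")
  )
  if (!is.null(viability)) {
    excluded <- viability$chamber[!viability$viable]
    lines <- c(lines,
      sprintf("Chambers analysed: %d of %d%s",
              sum(viability$viable), nrow(viability),
              if (length(excluded)) {
                paste0(" (excluded: chamber ",
                       paste(excluded, collapse = ", chamber "), ")")
              } else "")
    )
  }
  list(table = long, summary = lines)
}

#' Write a rendered report to disk
#'
#' @param report A [render_report()] result.
#' @param dir Output directory (created if needed); writes `report.csv` and
#'   `summary.txt`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$table, file.path(dir, "report.csv"), na = "")
  writeLines(report$summary, file.path(dir, "summary.txt"))
  invisible(dir)
}
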