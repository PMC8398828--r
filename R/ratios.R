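ratio_kinds <- c("ACC100_DON0", "ACC100_DON100", "MEM_DON0",
                 "MEM_DON100", "DON100_DON0")

#' Semi-quantitative compartment ratios of peak heights
#'
#' For each matched compound, computes the percentage ratio of peak heights
#' between compartments:
#'
#' * `ACC100_DON0` — acceptor at end time / donor at time 0
#' * `ACC100_DON100` — acceptor at end time / donor at end time
#' * `MEM_DON0` — extracted membrane / donor at time 0
#' * `MEM_DON100` — extracted membrane / donor at end time
#' * `DON100_DON0` — donor at end time / donor at time 0
#'
#' Ratios with an end-time denominator are computed within chamber (the
#' chamber is the experimental unit) and then aggregated as mean, SD and CV
#' over chambers. Time-0 denominators use the mean height over the donor
#' time-0 samples, falling back to the stock-solution analytical replicates
#' when no donor time-0 samples exist. A censored (below-LOD) numerator
#' contributes 0 with status `below_lod_numerator` rather than being dropped,
#' which avoids upward bias; a fully censored denominator gives status
#' `below_lod_denominator` and an undefined value.
#'
#' @param table A [feature_table].
#' @param matches Output of [match_targets()].
#' @param kinds Which ratio kinds to compute (default all five).
#' @return A tibble with one row per compound and kind: `compound_id`,
#'   `ratio_kind`, `n`, `mean`, `sd`, `cv` (all percent), `status`, and a
#'   `replicates` list-column of per-chamber values.
#' @export
compute_ratios <- function(table, matches, kinds = ratio_kinds) {
  stopifnot(inherits(table, "feature_table"))
  kinds <- match.arg(kinds, ratio_kinds, several.ok = TRUE)
  info <- sample_info(table)
  end_time <- max(info$time[info$compartment %in%
                              c("donor", "acceptor", "membrane")])
  grids <- tidyr::expand_grid(compound_id = matches$compound_id,
                              ratio_kind = kinds)
  purrr::pmap_dfr(grids, function(compound_id, ratio_kind) {
    fid <- matches$feature_id[matches$compound_id == compound_id]
    compute_one_ratio(table, info, compound_id, fid, ratio_kind, end_time)
  })
}

heights_for <- function(table, fid, cols) {
  if (length(cols) == 0 || is.na(fid)) return(numeric(0))
  as.numeric(unlist(table[table$feature_id == fid, cols, drop = FALSE]))
}

compute_one_ratio <- function(table, info, compound_id, fid, kind, end_time) {
  result <- function(values, status, num_detected = NA, den_detected = NA) {
    ok <- status %in% c("ok", "below_lod_numerator")
    m <- if (ok && length(values)) mean(values) else NA_real_
    s <- if (ok && length(values) > 1) stats::sd(values) else NA_real_
    tibble::tibble(
      compound_id = compound_id, ratio_kind = kind,
      n = length(values), mean = m, sd = s,
      cv = if (!is.na(m) && !is.na(s) && m > 0) s / m * 100 else NA_real_,
      status = status,
      numerator_detected = num_detected,
      denominator_detected = den_detected,
      replicates = list(values)
    )
  }
  if (is.na(fid)) return(result(numeric(0), "unmatched"))

  sel <- function(compartment, time = NULL) {
    idx <- info$compartment == compartment
    if (!is.null(time)) idx <- idx & info$time == time
    info[idx, , drop = FALSE]
  }
  don0 <- sel("donor", 0)
  if (nrow(don0) == 0) don0 <- sel("stock")
  den0 <- heights_for(table, fid, don0$sample_id)

  num_info <- switch(kind,
    ACC100_DON0 = , ACC100_DON100 = sel("acceptor", end_time),
    MEM_DON0 = , MEM_DON100 = sel("membrane"),
    DON100_DON0 = sel("donor", end_time)
  )
  num_info <- dplyr::arrange(num_info, .data$replicate)
  num <- heights_for(table, fid, num_info$sample_id)

  num_detected <- length(num) > 0 && !all(is.na(num))
  if (kind %in% c("ACC100_DON0", "MEM_DON0", "DON100_DON0")) {
    if (length(den0) == 0 || all(is.na(den0))) {
      return(result(numeric(0), "below_lod_denominator", num_detected, FALSE))
    }
    den <- mean(den0, na.rm = TRUE)
    vals <- 100 * ifelse(is.na(num), 0, num) / den
    status <- if (!num_detected) "below_lod_numerator" else "ok"
    return(result(vals, status, num_detected, TRUE))
  }
  # end-time denominators: pair numerator and denominator within chamber
  den_info <- dplyr::arrange(sel("donor", end_time), .data$replicate)
  den <- heights_for(table, fid, den_info$sample_id)
  den <- den[match(num_info$replicate, den_info$replicate)]
  keep <- !is.na(den)
  if (!any(keep)) {
    return(result(numeric(0), "below_lod_denominator", num_detected, FALSE))
  }
  vals <- 100 * ifelse(is.na(num[keep]), 0, num[keep]) / den[keep]
  status <- if (!num_detected) "below_lod_numerator" else "ok"
  result(vals, status, num_detected, TRUE)
}

#' Call compounds permeant from the acceptor/donor-0 ratio
#'
#' A compound counts as a permeant when its mean acceptor(end)/donor(0) peak
#' height ratio reaches the detectability threshold (default 0.1%): even such
#' small acceptor signals indicate genuine transfer across the membrane.
#'
#' @param ratios Output of [compute_ratios()] containing `ACC100_DON0` rows.
#' @param threshold Percent ratio at or above which a compound is a permeant.
#' @return A tibble `compound_id`, `acc_don0_ratio`, `permeant`.
#' @export
permeant_call <- function(ratios, threshold = 0.1) {
  rows <- dplyr::filter(ratios, .data$ratio_kind == "ACC100_DON0")
  if (nrow(rows) == 0) stop("no ACC100_DON0 ratios supplied", call. = FALSE)
  out <- tibble::tibble(
    compound_id = rows$compound_id,
    acc_don0_ratio = rows$mean,
    permeant = rows$status == "ok" & !is.na(rows$mean) &
      rows$mean >= threshold
  )
  attr(out, "threshold") <- threshold
  out
}
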