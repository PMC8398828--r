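#' Aligned LC-MS feature tables
#'
#' A feature table is a wide tibble with one row per aligned LC-MS feature.
#' The first three columns are `feature_id`, `mz` (Th, \[M+H\]+) and `rt`
#' (min); every remaining column is one measured sample whose name encodes
#' its metadata with the grammar `<compartment>_t<min>_r<replicate>`, e.g.
#' `donor_t0_r1`, `acceptor_t100_r3`, `blank_membrane_t100_r1`. Cell values
#' are peak heights; an empty cell (`NA`) is a censored/absent feature.
#'
#' @param x A data frame in the layout above.
#' @return `feature_table()` returns the validated object (class
#'   `feature_table`).
#' @export
feature_table <- function(x) {
  new_feature_table(tibble::as_tibble(x))
}

new_feature_table <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("feature_id", "mz", "rt")
  if (!all(need %in% names(x)[1:3])) {
    stop("malformed header: first columns must be feature_id, mz, rt",
         call. = FALSE)
  }
  sample_cols <- setdiff(names(x), need)
  dup <- sample_cols[duplicated(sample_cols)]
  if (length(dup)) {
    stop("duplicate sample column: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$feature_id)) {
    stop("duplicate feature_id", call. = FALSE)
  }
  if (!all(is.finite(x$mz)) || !all(is.finite(x$rt)) ||
      any(x$mz <= 0) || any(x$rt < 0)) {
    stop("mz and rt must be finite, mz > 0 and rt >= 0", call. = FALSE)
  }
  parse_sample_names(sample_cols) # validates the grammar
  for (col in sample_cols) {
    if (!is.numeric(x[[col]])) {
      stop("non-numeric intensity in column '", col, "'", call. = FALSE)
    }
  }
  class(x) <- unique(c("feature_table", class(x)))
  x
}

parse_sample_names <- function(nm) {
  m <- regmatches(nm, regexec("^([a-z_]+)_t([0-9]+(?:\\.[0-9]+)?)_r([0-9]+)$",
                              nm))
  bad <- nm[vapply(m, length, 1L) != 4L]
  if (length(bad)) {
    stop("sample column name(s) not of the form <compartment>_t<min>_r<rep>: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  compartments <- c("stock", "donor", "acceptor", "membrane",
                    "blank_membrane", "blank_buffer", "calibration")
  out <- tibble::tibble(
    sample_id = nm,
    compartment = vapply(m, `[[`, "", 2L),
    time = as.numeric(vapply(m, `[[`, "", 3L)),
    replicate = as.integer(vapply(m, `[[`, "", 4L))
  )
  unknown <- setdiff(unique(out$compartment), compartments)
  if (length(unknown)) {
    stop("unknown compartment(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out$chamber <- ifelse(out$compartment %in% c("donor", "acceptor", "membrane"),
                        out$replicate, NA_integer_)
  out
}

#' Sample metadata of a feature table
#'
#' Decodes the sample-column names into a tidy table of compartment, sampling
#' time, replicate index and chamber id (replicate chambers are the
#' experimental unit; stock and blank samples carry no chamber).
#'
#' @param table A [feature_table].
#' @return A tibble `sample_id`, `compartment`, `time`, `replicate`,
#'   `chamber`.
#' @export
sample_info <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  parse_sample_names(setdiff(names(table), c("feature_id", "mz", "rt")))
}

#' Read / write a feature-table CSV
#'
#' The CSV dialect is comma-separated UTF-8 with `.` decimal marks; an empty
#' cell is a censored (absent) intensity. `read_feature_table()` and
#' [write_feature_table()] round-trip losslessly.
#'
#' @param path File path.
#' @return A [feature_table].
#' @export
read_feature_table <- function(path) {
  header <- strsplit(readr::read_lines(path, n_max = 1), ",")[[1]]
  dup <- header[duplicated(header)]
  if (length(dup)) {
    stop("duplicate sample column: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  x <- readr::read_csv(path, col_types = readr::cols(
    feature_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE, name_repair = "minimal")
  new_feature_table(x)
}

#' @param table A [feature_table].
#' @rdname read_feature_table
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  readr::write_csv(tibble::as_tibble(table), path, na = "")
  invisible(path)
}

#' Build a target list for matching compounds to features
#'
#' @param compounds A [compound_table()].
#' @param ppm_tol m/z tolerance (ppm).
#' @param rt_tol Retention-time tolerance (min).
#' @return A `target_list` object (tibble with tolerance attributes).
#' @export
target_list <- function(compounds, ppm_tol = 5, rt_tol = 0.1) {
  stopifnot(ppm_tol > 0, rt_tol > 0)
  out <- tibble::as_tibble(compounds)
  attr(out, "ppm_tol") <- ppm_tol
  attr(out, "rt_tol") <- rt_tol
  class(out) <- unique(c("target_list", class(out)))
  out
}

#' Match target compounds to aligned features
#'
#' Targeted feature assignment by m/z and retention time: a feature is a
#' candidate for a compound when its relative m/z error is within `ppm_tol`
#' and its retention-time error within `rt_tol`. Among several candidates the
#' smallest ppm error wins, ties broken by smallest RT error; features are
#' assigned one-to-one, greedily in order of increasing ppm error, so a
#' single feature can never quantify two co-eluting isomers.
#'
#' @param table A [feature_table].
#' @param targets A [target_list()] (or a [compound_table()], matched with
#'   default tolerances).
#' @return A tibble `compound_id`, `feature_id` (NA when unmatched),
#'   `ppm_error`, `rt_error`, `matched`. Row order follows the target list;
#'   the result is independent of feature-row order.
#' @export
match_targets <- function(table, targets) {
  stopifnot(inherits(table, "feature_table"))
  if (!inherits(targets, "target_list")) targets <- target_list(targets)
  ppm_tol <- attr(targets, "ppm_tol")
  rt_tol <- attr(targets, "rt_tol")
  if (nrow(table) == 0) stop("empty feature table", call. = FALSE)

  cand <- tidyr::expand_grid(
    tibble::tibble(compound_id = targets$id, target_mz = targets$mz,
                   target_rt = targets$rt),
    tibble::tibble(feature_id = table$feature_id, mz = table$mz,
                   rt = table$rt)
  )
  cand <- dplyr::mutate(
    cand,
    ppm_error = abs(.data$mz - .data$target_mz) / .data$target_mz * 1e6,
    rt_error = abs(.data$rt - .data$target_rt)
  )
  cand <- dplyr::filter(cand, .data$ppm_error <= ppm_tol,
                        .data$rt_error <= rt_tol)
  # deterministic greedy one-to-one assignment by ppm error, then RT error;
  # compound_id/feature_id break exact ties so row order never matters
  cand <- dplyr::arrange(cand, .data$ppm_error, .data$rt_error,
                         .data$compound_id, .data$feature_id)
  assigned <- character(0)
  taken <- character(0)
  picks <- list()
  for (i in seq_len(nrow(cand))) {
    row <- cand[i, ]
    if (row$compound_id %in% assigned || row$feature_id %in% taken) next
    assigned <- c(assigned, row$compound_id)
    taken <- c(taken, row$feature_id)
    picks[[length(picks) + 1L]] <- row
  }
  picks <- dplyr::bind_rows(picks)
  out <- tibble::tibble(compound_id = targets$id)
  if (nrow(picks)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(picks, "compound_id", "feature_id", "ppm_error",
                    "rt_error"),
      by = "compound_id"
    )
  } else {
    out$feature_id <- NA_character_
    out$ppm_error <- NA_real_
    out$rt_error <- NA_real_
  }
  dplyr::mutate(out, matched = !is.na(.data$feature_id))
}

#' Flag compounds whose membrane signal is confounded by the blank membrane
#'
#' Tissue blanks (membrane incubated in buffer without the test solution)
#' reveal endogenous interferences, e.g. dietary isoflavones. A compound is
#' flagged when its mean blank-membrane height exceeds `blank_ratio_max`
#' times its mean membrane height; flagged compounds should be excluded from
#' membrane-based ratios downstream.
#'
#' @param table A [feature_table].
#' @param matches Output of [match_targets()].
#' @param blank_ratio_max Maximum tolerated blank/membrane height ratio.
#' @return A tibble `compound_id`, `membrane_height`, `blank_height`,
#'   `interference`, `status` (`"ok"`, `"not_detected"` when the compound is
#'   absent from the membrane, `"no_blank"` when no blank samples exist).
#' @export
check_blank_interference <- function(table, matches, blank_ratio_max = 0.1) {
  stopifnot(inherits(table, "feature_table"))
  info <- sample_info(table)
  mem_cols <- info$sample_id[info$compartment == "membrane"]
  blank_cols <- info$sample_id[info$compartment == "blank_membrane"]
  no_blank <- length(blank_cols) == 0
  if (no_blank) {
    warning("no blank_membrane samples; interference flags all FALSE",
            call. = FALSE)
  }
  mean_height <- function(feature_id, cols) {
    if (is.na(feature_id) || length(cols) == 0) return(NA_real_)
    v <- unlist(table[table$feature_id == feature_id, cols, drop = FALSE])
    if (all(is.na(v))) return(0)
    mean(ifelse(is.na(v), 0, v))
  }
  purrr::map_dfr(seq_len(nrow(matches)), function(i) {
    fid <- matches$feature_id[i]
    mh <- mean_height(fid, mem_cols)
    bh <- mean_height(fid, blank_cols)
    detected <- !is.na(mh) && mh > 0
    tibble::tibble(
      compound_id = matches$compound_id[i],
      membrane_height = mh,
      blank_height = bh,
      interference = if (no_blank || !detected) FALSE else
        isTRUE(bh > blank_ratio_max * mh),
      status = if (no_blank) "no_blank" else
        if (!detected) "not_detected" else "ok"
    )
  })
}
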