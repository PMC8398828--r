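#' Fit an external calibration curve with ICH Q2(R1) detection limits
#'
#' Fits ordinary least squares of response on concentration separately for
#' each replicate calibration series. The pooled slope is the mean of the
#' per-replicate slopes and the response standard deviation is the SD of the
#' per-replicate y-intercepts ("standard deviation of the response and the
#' slope" method); the detection and quantification limits are then
#' `LOD = 3.3 sigma / S` and `LOQ = 10 sigma / S`. With a single replicate
#' series the residual standard error replaces the intercept SD and the
#' curve is flagged (`sigma_source = "residual"`).
#'
#' @param data A data frame with columns `level` (concentration, nM),
#'   `replicate` and `response` (peak height or area), and optionally
#'   `compound_id` (a single value).
#' @return An object of class `calibration_curve`.
#' @export
fit_calibration <- function(data) {
  stopifnot(all(c("level", "replicate", "response") %in% names(data)))
  compound_id <- if ("compound_id" %in% names(data)) {
    unique(data$compound_id)
  } else "compound"
  stopifnot(length(compound_id) == 1)
  levels <- sort(unique(data$level))
  if (length(levels) < 3) {
    stop("need at least 3 calibration levels", call. = FALSE)
  }

  fits <- data |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_map(~ stats::lm(response ~ level, data = .x))
  slopes <- vapply(fits, function(f) stats::coef(f)[["level"]], 1)
  intercepts <- vapply(fits, function(f) stats::coef(f)[["(Intercept)"]], 1)

  slope <- mean(slopes)
  if (slope <= 0) stop("non-positive calibration slope", call. = FALSE)
  if (length(fits) >= 2) {
    sigma <- stats::sd(intercepts)
    sigma_source <- "intercepts"
  } else {
    sigma <- stats::sigma(fits[[1]])
    sigma_source <- "residual"
  }
  pooled <- stats::lm(response ~ level, data = data)

  structure(
    list(
      compound_id = compound_id,
      levels = levels,
      n_replicates = length(fits),
      slope = slope,
      intercept = mean(intercepts),
      sigma_intercept = sigma,
      sigma_source = sigma_source,
      lod = 3.3 * sigma / slope,
      loq = 10 * sigma / slope,
      r2 = r_squared(pooled),
      data = tibble::as_tibble(data)
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %s: slope %.4g, LOD %.3g nM, LOQ %.3g nM, R2 %.4f\n",
    x$compound_id, x$slope, x$lod, x$loq, x$r2))
  if (x$sigma_source == "residual") {
    cat("  (sigma from residual SD: single replicate series)\n")
  }
  invisible(x)
}

#' @method tidy calibration_curve
#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept)
  )
}

#' @method glance calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(
    compound_id = x$compound_id,
    slope = x$slope, intercept = x$intercept,
    sigma_intercept = x$sigma_intercept, sigma_source = x$sigma_source,
    lod = x$lod, loq = x$loq, r2 = x$r2,
    n_levels = length(x$levels), n_replicates = x$n_replicates
  )
}


# R^2 without summary.lm's perfect-fit warning (exact synthetic lines are a
# legitimate input here)
r_squared <- function(fit) {
  y <- fit$model[[1]]
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / ss_tot
}

#' Quantify responses against a calibration curve
#'
#' Converts responses to concentrations as
#' `(response - intercept) / slope` and annotates each value with its censor
#' status: `below_lod` (kept for diagnostics but to be treated as zero in
#' amount sums), `between_lod_loq` (flagged, still used), `ok`, or `invalid`
#' for responses that are negative after blank correction.
#'
#' @param response Numeric vector of responses (same units as the curve).
#' @param curve A [fit_calibration()] result.
#' @return A tibble `response`, `conc` (nM), `status`.
#' @export
quantify <- function(response, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  conc <- (response - curve$intercept) / curve$slope
  status <- dplyr::case_when(
    response < 0 ~ "invalid",
    conc < curve$lod ~ "below_lod",
    conc < curve$loq ~ "between_lod_loq",
    TRUE ~ "ok"
  )
  tibble::tibble(response = response, conc = conc, status = status)
}

#' Simulate a replicate calibration series
#'
#' Generates proportional responses `slope x level` at the given levels with
#' multiplicative lognormal noise, the same error model as the measurement
#' simulator, for exercising LOD/LOQ estimation.
#'
#' @param levels Concentration levels (nM).
#' @param slope True response per nM.
#' @param noise_cv Coefficient of variation of the noise.
#' @param n_replicates Number of replicate series.
#' @param seed Integer seed.
#' @param compound_id Label carried into the output.
#' @return A tibble `compound_id`, `level`, `replicate`, `response`.
#' @export
simulate_calibration <- function(levels = c(2, 5, 10, 20, 50),
                                 slope = 3e3, noise_cv = 0.10,
                                 n_replicates = 3, seed = 1L,
                                 compound_id = "compound") {
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  tidyr::expand_grid(replicate = seq_len(n_replicates), level = levels) |>
    dplyr::mutate(
      compound_id = compound_id,
      response = slope * .data$level *
        if (noise_cv > 0) {
          stats::rlnorm(dplyr::n(), meanlog = -sdlog^2 / 2, sdlog = sdlog)
        } else 1
    ) |>
    dplyr::select("compound_id", "level", "replicate", "response")
}
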