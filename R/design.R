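#' Describe the geometry and sampling schedule of one Ussing-chamber run
#'
#' An experiment design bundles everything that is fixed before the tissue is
#' mounted: compartment volumes, exposed membrane area, the aliquot-sampling
#' schedule with its replacement policy, the number of replicate chambers and
#' the TEER viability threshold. Defaults reproduce a porcine-jejunum setup:
#' 7 mL half-cells, 1.26 cm2 exposed area, sampling at 0, 10, 20, 40, 60, 80
#' and 100 min with 400 uL acceptor aliquots replaced by fresh buffer and
#' donor aliquots replaced by stock solution, four chambers, and a 15 Ohm cm2
#' viability floor.
#'
#' @param donor_volume,acceptor_volume Compartment volumes (mL).
#' @param exposed_area Exposed membrane area (cm2).
#' @param sampling_times Strictly increasing sampling times (min) starting at 0.
#' @param donor_aliquot,acceptor_aliquot Aliquot volumes withdrawn at each
#'   sampling time (mL). Use 0.2 for extract runs, 0.1 for pure-standard runs.
#' @param donor_replacement `"stock_solution"` (withdrawn donor volume replaced
#'   by stock at the initial concentration) or `"fresh_buffer"` (dilution).
#' @param acceptor_replacement Only `"fresh_buffer"` is meaningful.
#' @param n_replicates Number of replicate chambers.
#' @param teer_threshold Viability threshold (Ohm cm2); tissues whose TEER
#'   falls below it are excluded from analysis.
#' @param extract_volume Nominal volume (mL) in which the membrane is extracted
#'   at the end of the run; used only to turn tissue amounts into a measurable
#'   concentration and back.
#'
#' @return An object of class `chamber_design` (a list).
#' @export
chamber_design <- function(donor_volume = 7,
                           acceptor_volume = 7,
                           exposed_area = 1.26,
                           sampling_times = c(0, 10, 20, 40, 60, 80, 100),
                           donor_aliquot = 0.2,
                           acceptor_aliquot = 0.4,
                           donor_replacement = c("stock_solution", "fresh_buffer"),
                           acceptor_replacement = "fresh_buffer",
                           n_replicates = 4,
                           teer_threshold = 15,
                           extract_volume = 7) {
  donor_replacement <- match.arg(donor_replacement)
  acceptor_replacement <- match.arg(acceptor_replacement)
  stopifnot(
    donor_volume > 0, acceptor_volume > 0, exposed_area > 0,
    extract_volume > 0,
    length(sampling_times) >= 2,
    sampling_times[1] == 0,
    all(diff(sampling_times) > 0),
    donor_aliquot >= 0, donor_aliquot < donor_volume,
    acceptor_aliquot >= 0, acceptor_aliquot < acceptor_volume,
    n_replicates >= 1, teer_threshold >= 0
  )
  structure(
    list(
      donor_volume = donor_volume,
      acceptor_volume = acceptor_volume,
      exposed_area = exposed_area,
      sampling_times = as.numeric(sampling_times),
      donor_aliquot = donor_aliquot,
      acceptor_aliquot = acceptor_aliquot,
      donor_replacement = donor_replacement,
      acceptor_replacement = acceptor_replacement,
      duration = max(sampling_times),
      n_replicates = as.integer(n_replicates),
      teer_threshold = teer_threshold,
      extract_volume = extract_volume
    ),
    class = "chamber_design"
  )
}

#' @export
print.chamber_design <- function(x, ...) {
  cat("<chamber_design>\n")
  cat(sprintf("  donor/acceptor volume : %g / %g mL\n",
              x$donor_volume, x$acceptor_volume))
  cat(sprintf("  exposed area          : %g cm2\n", x$exposed_area))
  cat(sprintf("  sampling times (min)  : %s\n",
              paste(x$sampling_times, collapse = ", ")))
  cat(sprintf("  aliquots donor/accept : %g / %g mL (%s / %s)\n",
              x$donor_aliquot, x$acceptor_aliquot,
              x$donor_replacement, x$acceptor_replacement))
  cat(sprintf("  replicates            : %d chambers\n", x$n_replicates))
  cat(sprintf("  TEER threshold        : %g Ohm cm2\n", x$teer_threshold))
  invisible(x)
}

#' Build a table of monitored compounds
#'
#' Each row describes one compound tracked through the experiment: its LC-MS
#' coordinates (protonated m/z and retention time), molecular weight, chemical
#' class, and initial donor concentration. An initial concentration of zero
#' marks a compound only ever produced by intestinal biotransformation.
#'
#' @param id Short unique labels.
#' @param name Human-readable names (defaults to `id`).
#' @param mz m/z of the \[M+H\]+ ion (Th).
#' @param rt Retention time (min).
#' @param mw Molecular weight (g/mol).
#' @param compound_class One of `"C_glycoside"`, `"O_glycoside"`,
#'   `"malonyl_O_glycoside"`, `"aglycone"`, `"other"`.
#' @param initial_donor_conc Initial donor concentration (uM).
#'
#' @return A tibble with one row per compound.
#' @export
compound_table <- function(id, mz, rt, mw,
                           compound_class = "other",
                           initial_donor_conc = 0,
                           name = id) {
  classes <- c("C_glycoside", "O_glycoside", "malonyl_O_glycoside",
               "aglycone", "other")
  out <- tibble::tibble(
    id = as.character(id), name = as.character(name),
    mz = as.numeric(mz), rt = as.numeric(rt), mw = as.numeric(mw),
    compound_class = as.character(compound_class),
    initial_donor_conc = as.numeric(initial_donor_conc)
  )
  stopifnot(
    !anyDuplicated(out$id),
    all(out$mz > 0), all(out$rt >= 0), all(out$mw > 0),
    all(out$initial_donor_conc >= 0),
    all(out$compound_class %in% classes)
  )
  out
}

#' Per-compound kinetic parameters of the forward model
#'
#' Rates are first-order (1/min) except `papp_true`, the true transmembrane
#' permeability in cm/s. `k_deposit` moves compound from the donor solution
#' into the tissue; `k_release` lets tissue-bound compound leak into the
#' acceptor; `k_hydrolysis` converts a glycoside to its aglycone in the donor
#' compartment (mole for mole, feeding `hydrolysis_product`); `k_hydroxylation`
#' likewise feeds `hydroxylation_product`. The product graph must be acyclic.
#'
#' @param compound_id Compound labels (must match the compound table).
#' @param papp_true True permeability (cm/s).
#' @param k_deposit,k_release,k_hydrolysis,k_hydroxylation First-order rates
#'   (1/min).
#' @param hydrolysis_product,hydroxylation_product Product compound ids or
#'   `NA` for none.
#'
#' @return A tibble with one row per compound.
#' @export
kinetic_params <- function(compound_id,
                           papp_true = 0,
                           k_deposit = 0,
                           k_release = 0,
                           k_hydrolysis = 0,
                           hydrolysis_product = NA_character_,
                           k_hydroxylation = 0,
                           hydroxylation_product = NA_character_) {
  out <- tibble::tibble(
    compound_id = as.character(compound_id),
    papp_true = as.numeric(papp_true),
    k_deposit = as.numeric(k_deposit),
    k_release = as.numeric(k_release),
    k_hydrolysis = as.numeric(k_hydrolysis),
    hydrolysis_product = as.character(hydrolysis_product),
    k_hydroxylation = as.numeric(k_hydroxylation),
    hydroxylation_product = as.character(hydroxylation_product)
  )
  rates <- c(out$papp_true, out$k_deposit, out$k_release,
             out$k_hydrolysis, out$k_hydroxylation)
  stopifnot(!anyDuplicated(out$compound_id), all(rates >= 0))
  check_acyclic_products(out)
  out
}

# reaction graph must not cycle: a compound may not (transitively) produce itself
check_acyclic_products <- function(kin) {
  edges <- rbind(
    data.frame(from = kin$compound_id, to = kin$hydrolysis_product),
    data.frame(from = kin$compound_id, to = kin$hydroxylation_product)
  )
  edges <- edges[!is.na(edges$to), , drop = FALSE]
  if (nrow(edges) == 0) return(invisible(TRUE))
  reach <- function(start) {
    seen <- character(0); frontier <- start
    while (length(frontier)) {
      nxt <- edges$to[edges$from %in% frontier]
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    seen
  }
  for (cid in unique(edges$from)) {
    if (cid %in% reach(cid)) {
      stop("cyclic product graph: compound '", cid,
           "' transitively produces itself", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Measurement model for turning true concentrations into peak heights
#'
#' Peak heights are proportional to concentration with a per-compound response
#' factor, perturbed by multiplicative lognormal noise of fixed coefficient of
#' variation, and censored to absent below a height floor. The defaults put
#' the detection limit near 5 nM (floor 1.5e4 counts at 3e6 counts per uM),
#' the sensitivity regime of a high-resolution LC-MS metabolomics method.
#'
#' @param response_factor Peak-height units per uM; either a single value or a
#'   named vector keyed by compound id.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (fraction; 0 = noise-free).
#' @param lod_height Height floor below which a feature is censored to absent.
#'
#' @return An object of class `measurement_model`.
#' @export
measurement_model <- function(response_factor = 3e6,
                              noise_cv = 0,
                              lod_height = 1.5e4) {
  stopifnot(all(response_factor > 0), noise_cv >= 0, lod_height >= 0)
  structure(
    list(response_factor = response_factor,
         noise_cv = noise_cv,
         lod_height = lod_height),
    class = "measurement_model"
  )
}

response_factor_for <- function(model, compound_id) {
  rf <- model$response_factor
  if (is.null(names(rf))) return(rep(rf[[1]], length(compound_id)))
  missing <- setdiff(compound_id, names(rf))
  if (length(missing)) {
    stop("no response factor for compound(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unname(rf[compound_id])
}
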