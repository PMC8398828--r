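isoflavone_targets <- function() {
  compound_table(
    id = c("puerarin", "daidzin", "daidzein", "hydroxypuerarin"),
    mz = c(417.1181, 417.1181, 255.0652, 433.1131),
    rt = c(2.20, 3.31, 6.86, 1.51),
    mw = c(416.38, 416.38, 254.24, 432.38),
    compound_class = c("C_glycoside", "O_glycoside", "aglycone",
                       "C_glycoside"),
    initial_donor_conc = c(25, 5, 0.1, 1)
  )
}

fate_of <- function(fate, cid) fate$label[fate$compound_id == cid]

test_that("archetypal compartment profiles receive their expected labels", {
  ratios <- dplyr::bind_rows(
    # stable C-glycoside detected in the acceptor
    ratio_row("puerarin", "DON100_DON0", 99),
    ratio_row("puerarin", "ACC100_DON0", 0.5),
    ratio_row("puerarin", "MEM_DON100", 0.5),
    # O-glycoside that vanished from the donor
    ratio_row("daidzin", "DON100_DON0", 2),
    ratio_row("daidzin", "ACC100_DON0", 0, status = "below_lod_numerator",
              num_detected = FALSE),
    # aglycone with a time-0 trace that exploded in the donor
    ratio_row("daidzein", "DON100_DON0", 774),
    ratio_row("daidzein", "ACC100_DON0", 0, status = "below_lod_numerator",
              num_detected = FALSE),
    ratio_row("daidzein", "MEM_DON100", 13.4),
    # tri-hydroxylated C-glycoside one oxygen above puerarin
    ratio_row("hydroxypuerarin", "DON100_DON0", 200),
    ratio_row("hydroxypuerarin", "ACC100_DON0", 0,
              status = "below_lod_numerator", num_detected = FALSE)
  )
  fate <- classify_fate(ratios, permeant_call(ratios),
                        targets = isoflavone_targets())
  expect_equal(fate_of(fate, "puerarin"), "permeant")
  expect_equal(fate_of(fate, "daidzin"), "depleted_precursor")
  expect_equal(fate_of(fate, "daidzein"), "intestinal_metabolite")
  expect_equal(fate_of(fate, "hydroxypuerarin"), "hydroxylation_product")

  # membrane retention appears in the metabolite's evidence trail
  ev <- fate$evidence[fate$compound_id == "daidzein"][[1]]
  expect_true("MEM_DON100" %in% ev$ratio_kind)

  # classification is a pure function: identical inputs, identical labels
  expect_identical(fate, classify_fate(ratios, permeant_call(ratios),
                                       targets = isoflavone_targets()))
})

test_that("interference and non-detection take precedence", {
  ratios <- dplyr::bind_rows(
    ratio_row("dirty", "DON100_DON0", 100),
    ratio_row("dirty", "ACC100_DON0", 5),
    ratio_row("ghost", "DON100_DON0", NA, status = "below_lod_denominator",
              num_detected = FALSE, den_detected = FALSE),
    ratio_row("ghost", "ACC100_DON0", 0, status = "below_lod_numerator",
              num_detected = FALSE)
  )
  interference <- tibble::tibble(compound_id = c("dirty", "ghost"),
                                 interference = c(TRUE, FALSE))
  fate <- classify_fate(ratios, permeant_call(ratios), interference)
  expect_equal(fate_of(fate, "dirty"), "interference_excluded")
  expect_equal(fate_of(fate, "ghost"), "not_detected")
})

test_that("a malonyl glycoside stays stable while its plain counterpart depletes", {
  des <- design_extract()
  cmp <- compound_table(
    id = c("glycoside", "malonyl", "aglycone"),
    mz = c(417.1181, 503.1186, 255.0652), rt = c(3.31, 5.94, 6.86),
    mw = c(416.38, 502.42, 254.24),
    compound_class = c("O_glycoside", "malonyl_O_glycoside", "aglycone"),
    initial_donor_conc = c(10, 10, 0)
  )
  # the malonyl group shields the sugar: ~20x slower hydrolysis, leaving
  # ~84% in the donor at 100 min while the plain O-glycoside collapses
  kin <- kinetic_params(
    c("glycoside", "malonyl", "aglycone"),
    k_hydrolysis = c(0.03, log(100 / 84) / 100, 0),
    hydrolysis_product = c("aglycone", "aglycone", NA)
  )
  run <- simulate_experiment(des, cmp, kin, seed = 21)
  m <- match_targets(run$table, target_list(cmp))
  ratios <- compute_ratios(run$table, m)
  fate <- classify_fate(ratios, permeant_call(ratios), targets = cmp)
  expect_equal(fate_of(fate, "malonyl"), "stable_in_donor")
  expect_equal(fate_of(fate, "glycoside"), "depleted_precursor")
  expect_equal(fate_of(fate, "aglycone"), "intestinal_metabolite")
  don <- ratios[ratios$compound_id == "malonyl" &
                  ratios$ratio_kind == "DON100_DON0", ]
  # stock replacement tops the donor back up, so the measured ratio sits a
  # touch above the no-sampling closed form
  expect_equal(don$mean, 84, tolerance = 0.03)
})

test_that("labels agree with generating kinetics across a 20-scenario grid", {
  des <- design_extract()
  grid <- tidyr::expand_grid(
    archetype = c("stable", "permeant", "hydrolysed", "slow_hydrolysis"),
    level = 1:5
  )
  results <- purrr::pmap_chr(grid, function(archetype, level) {
    papp <- switch(archetype, permeant = c(2, 4, 6, 8, 10)[level] * 1e-6, 0)
    k_hyd <- switch(archetype,
                    hydrolysed = c(0.01, 0.02, 0.03, 0.04, 0.05)[level],
                    slow_hydrolysis = c(0.5, 0.8, 1.1, 1.4, 1.7)[level] * 1e-3,
                    0)
    cmp <- compound_table(
      id = c("parent", "product"),
      mz = c(417.1181, 255.0652), rt = c(3.31, 6.86),
      mw = c(416.38, 254.24),
      compound_class = c("O_glycoside", "aglycone"),
      initial_donor_conc = c(50, 0)
    )
    kin <- kinetic_params(c("parent", "product"),
                          papp_true = c(papp, 0),
                          k_hydrolysis = c(k_hyd, 0),
                          hydrolysis_product = c("product", NA))
    run <- simulate_experiment(des, cmp, kin, seed = 100 + level)
    m <- match_targets(run$table, target_list(cmp))
    ratios <- compute_ratios(run$table, m)
    fate <- classify_fate(ratios, permeant_call(ratios), targets = cmp)
    fate$label[fate$compound_id == "parent"]
  })
  expected <- dplyr::case_match(grid$archetype,
                                "stable" ~ "stable_in_donor",
                                "permeant" ~ "permeant",
                                "hydrolysed" ~ "depleted_precursor",
                                "slow_hydrolysis" ~ "stable_in_donor")
  expect_equal(results, expected)
})

test_that("the rendered report aggregates every output deterministically", {
  sc <- get_scenario("pure_daidzin")
  run <- simulate_experiment(sc$design, sc$compounds, sc$kinetics, seed = 6)
  m <- match_targets(run$table, target_list(sc$compounds))
  ratios <- compute_ratios(run$table, m)
  fate <- classify_fate(ratios, permeant_call(ratios),
                        targets = sc$compounds)
  gate <- teer_gate(dplyr::bind_rows(
    tibble::tibble(chamber = 1:3, time_min = 0, resistance = 40) |>
      tidyr::uncount(2) |> dplyr::mutate(time_min = rep(c(0, 100), 3)),
    tibble::tibble(chamber = 4, time_min = c(0, 100), resistance = c(40, 10))
  ))
  rep <- render_report(ratios, fate, viability = gate)
  expect_true(all(c("table", "summary") %in% names(rep)))
  expect_equal(sort(unique(rep$table$compound_id)),
               sort(sc$compounds$id))
  # no acceptor signal anywhere: the summary reports no permeants
  expect_true(any(grepl("Permeants: none", rep$summary)))
  expect_true(any(grepl("excluded: chamber 4", rep$summary)))
  expect_true(any(grepl("3 of 4", rep$summary)))

  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "report.csv")))
  expect_true(file.exists(file.path(dir, "summary.txt")))

  expect_error(render_report(ratios, fate[-1, ]), "ids differ")
})
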