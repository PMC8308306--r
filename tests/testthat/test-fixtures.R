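# calibrated Benin/Ghana fixtures, synthetic generator, brute-force oracle

test_that("build_fixture is deterministic and rejects invalid cells", {
  a <- build_fixture("benin", "urban", "npnl")
  b <- build_fixture("benin", "urban", "npnl")
  expect_identical(a$manifest, b$manifest)
  expect_equal(as.numeric(daily_intake(a$scenario, a$table)),
               as.numeric(daily_intake(b$scenario, b$table)))
  expect_error(build_fixture("togo", "urban", "npnl"))
})

test_that("every basal cell reproduces its published Diet row at 1 dp", {
  for (i in seq_len(nrow(ALL_CELLS))) {
    fx <- build_fixture(ALL_CELLS$country[i], ALL_CELLS$setting[i],
                        ALL_CELLS$group[i])
    got <- round_half_away(as.numeric(daily_intake(fx$scenario, fx$table)), 1)
    want <- as.numeric(unlist(fx$manifest$targets$diet))
    expect_equal(got, want, tolerance = 1e-9,
                 info = paste("cell", fx$manifest$cell))
  }
})

test_that("fortified rows match published values up to recorded residuals", {
  for (i in seq_len(nrow(ALL_CELLS))) {
    fx <- build_fixture(ALL_CELLS$country[i], ALL_CELLS$setting[i],
                        ALL_CELLS$group[i])
    res <- compose_bundle(fx$bundles$diet_fortification, fx$table)
    computed <- as.numeric(res$total)
    printed <- as.numeric(unlist(fx$manifest$targets$fort))
    residual <- as.numeric(unlist(fx$manifest$fortified_row_residuals))
    # manifest bookkeeping: printed = computed + residual
    expect_equal(computed + residual, printed, tolerance = 1e-6,
                 info = paste("cell", fx$manifest$cell))
    # cells flagged consistent reproduce the printed row at table precision
    if (isTRUE(fx$manifest$fortified_row_consistent)) {
      expect_true(all(abs(residual) < pmax(0.25, 0.02 * printed)),
                  info = paste("cell", fx$manifest$cell))
    }
  }
})

test_that("calibrated vehicle masses match hand-derived quotients", {
  fx <- build_fixture("benin", "urban", "npnl")
  m <- fx$manifest$vehicle_masses_g
  expect_equal(m$oil, (1934 - 285) / 15, tolerance = 1e-9)     # ~109.9 g
  expect_equal(m$salt, 280.2 / iodate_to_iodine("KIO3", 35),
               tolerance = 1e-9)                               # ~13.5 g
  expect_equal(m$flour, (687 - 372) / 2.6, tolerance = 1e-9)   # ~121.2 g
  # rural cells carry no wheat flour
  expect_equal(build_fixture("benin", "rural", "npnl")$
                 manifest$vehicle_masses_g$flour, 0)
})

test_that("calibration is stable on the fixture's own outputs", {
  for (cc in c("benin", "ghana")) {
    fx <- build_fixture(cc, "urban", "pl")
    diet_row <- as.numeric(daily_intake(fx$scenario, fx$table))
    fort_row <- as.numeric(
      compose_bundle(fx$bundles$diet_fortification, fx$table)$total)
    names(diet_row) <- names(fort_row) <- nutrient_units()$nutrient
    cal <- calibrate_vehicle_masses(diet_row, fort_row, cc, "urban")
    expect_equal(as.list(cal$masses),
                 fx$manifest$vehicle_masses_g, tolerance = 1e-6)
    expect_true(all(abs(cal$residuals) < 1e-6))
  }
})

test_that("bundle availability follows the intervention matrix", {
  layer_names <- function(b) vapply(b$layers, function(l) l$name, character(1))
  for (i in seq_len(nrow(ALL_CELLS))) {
    cy <- ALL_CELLS$country[i]; st <- ALL_CELLS$setting[i]
    gr <- ALL_CELLS$group[i]
    fx <- build_fixture(cy, st, gr)
    all_names <- unique(unlist(lapply(fx$bundles, layer_names)))
    # wheat-flour fortification: urban only
    expect_equal("fortify_flour" %in% all_names, st == "urban",
                 info = fx$manifest$cell)
    # biofortification: Ghana only
    expect_equal("biofortify_maize" %in% all_names, cy == "ghana",
                 info = fx$manifest$cell)
    expect_equal("swap_osp_snack" %in% all_names, cy == "ghana",
                 info = fx$manifest$cell)
    # IFA: PL only; VAS: Ghana PL only
    expect_equal("ifa" %in% all_names, gr == "pl", info = fx$manifest$cell)
    expect_equal("vas" %in% all_names, cy == "ghana" && gr == "pl",
                 info = fx$manifest$cell)
    # tilapia for NPNL, fortified biscuit for PL
    expect_equal("add_tilapia" %in% all_names, gr == "npnl",
                 info = fx$manifest$cell)
    expect_equal("add_biscuit" %in% all_names, gr == "pl",
                 info = fx$manifest$cell)
    # mango and red-palm-oil swap everywhere; basal diet bundle has no layers
    expect_true(all(c("add_mango", "swap_red_palm_oil") %in% all_names))
    expect_length(fx$bundles$diet$layers, 0)
    # VAS never appears in the no-VAS combined bundles
    expect_false("vas" %in% layer_names(fx$bundles$all_mn_rich))
    expect_false("fortify_oil" %in% layer_names(fx$bundles$all_red_palm_oil))
  }
})

test_that("synthetic generator is seed-deterministic and valid", {
  a <- random_scenario(synthetic_config(seed = 123))
  b <- random_scenario(synthetic_config(seed = 123))
  expect_equal(as.numeric(compose_bundle(a$bundle, a$table)$total),
               as.numeric(compose_bundle(b$bundle, b$table)$total),
               tolerance = 1e-15)
  expect_identical(write_scenario(a$bundle$base), write_scenario(b$bundle$base))
  expect_error(synthetic_config(n_foods = 1))

  for (s in 1:100) {
    rs <- random_scenario(synthetic_config(seed = s, n_layers = s %% 4))
    tot <- as.numeric(compose_bundle(rs$bundle, rs$table)$total)
    expect_true(all(is.finite(tot)) && all(tot >= 0))
  }
})

test_that("oracle agrees with compose_bundle on fixtures and random bundles", {
  # all fixture bundles
  for (i in seq_len(nrow(ALL_CELLS))) {
    fx <- build_fixture(ALL_CELLS$country[i], ALL_CELLS$setting[i],
                        ALL_CELLS$group[i])
    for (bn in names(fx$bundles)) {
      impl <- as.numeric(compose_bundle(fx$bundles[[bn]], fx$table)$total)
      orac <- as.numeric(oracle_intake(fx$bundles[[bn]], fx$table))
      expect_equal(impl, orac, tolerance = 1e-9,
                   info = paste(fx$manifest$cell, bn))
    }
  }
  # seeded random bundles
  for (s in 1:200) {
    rs <- random_scenario(synthetic_config(seed = 20210722 + s,
                                           n_layers = s %% 5))
    impl <- as.numeric(compose_bundle(rs$bundle, rs$table)$total)
    orac <- as.numeric(oracle_intake(rs$bundle, rs$table))
    expect_equal(impl, orac, tolerance = 1e-9, info = paste("seed", s))
  }
})

test_that("fixture files are emitted and re-readable", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(dir)
  expect_true(all(file.exists(paths)))
  tab <- read_composition_table(file.path(dir, "composition_benin_urban_npnl.csv"))
  sc <- read_scenario(file.path(dir, "scenario_benin_urban_npnl.json"))
  got <- round_half_away(as.numeric(daily_intake(sc, tab)), 1)
  expect_equal(got, c(14.2, 8.0, 285, 9.9, 372, 0.8))
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(man$benin_urban_npnl$flour_levels_read_as, "elemental")
  refs <- read_reference_set(file.path(dir, "references.csv"))
  expect_equal(ref_get(refs, "iron", "npnl")$rni, 58.8)
})
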