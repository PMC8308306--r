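# Calibrated Benin/Ghana scenario fixtures (standing in for unavailable
# appendix menus and external composition tables), randomized synthetic
# scenarios, and the independent brute-force intake oracle.
#
# The eight country x setting x group cells are each represented as one
# calibrated "composite basal food" plus explicit vehicle foods (salt,
# vegetable oil, wheat-flour products, maize porridge, snacks). Composite
# compositions are back-calculated so each cell's basal intake reproduces
# its published "Diet" row exactly at printed precision; vehicle masses are
# back-calculated from the fortified-minus-basal deltas and the regulated
# fortification levels. Rows that the published tables print inconsistently
# are recorded as residuals in the manifest, never forced to agree.

FIXTURE_SEED <- 20210722L

fixture_cells <- function() {
  expand.grid(country = c("benin", "ghana"), setting = c("urban", "rural"),
              group = c("npnl", "pl"), stringsAsFactors = FALSE)
}

cell_id <- function(country, setting, group) {
  paste(country, setting, group, sep = "_")
}

# Published daily-intake rows (1 dp) used as calibration targets, in
# canonical nutrient order (iron, zinc, vitamin_a, niacin, folate, iodine).
# `diet` = basal diet; `fort` = diet + mandatory fortification;
# `suppl` = diet + fortification + supplementation (PL cells only).
fixture_targets <- function() {
  t <- function(x) stats::setNames(x, NUTRIENTS)
  list(
    benin_urban_npnl = list(diet = t(c(14.2, 8.0, 285, 9.9, 372, 0.8)),
                            fort = t(c(21.3, 14.5, 1934, 14.1, 687, 281))),
    benin_rural_npnl = list(diet = t(c(5.0, 2.5, 146, 3.9, 134, 0)),
                            fort = t(c(5.0, 2.5, 804, 3.9, 134, 354.2))),
    ghana_urban_npnl = list(diet = t(c(10.3, 5.7, 249, 9.4, 188, 0.3)),
                            fort = t(c(13.9, 7.4, 695, 13.0, 317, 107))),
    ghana_rural_npnl = list(diet = t(c(5.8, 3.6, 62, 9.1, 91, 0)),
                            fort = t(c(9.6, 5.4, 441, 12.9, 225, 41))),
    benin_urban_pl = list(diet = t(c(14.9, 8.4, 334, 9.9, 416, 20.8)),
                          fort = t(c(22.7, 15.5, 1544, 14.5, 749, 301)),
                          suppl = t(c(82.6, 15.5, 1544, 14.5, 1149, 301))),
    benin_rural_pl = list(diet = t(c(15.1, 5.4, 1036, 5.9, 150, 4.7)),
                          fort = t(c(15.1, 5.4, 2023, 5.9, 150, 568.2)),
                          suppl = t(c(75.1, 5.4, 2023, 5.9, 550, 568.2))),
    ghana_urban_pl = list(diet = t(c(7.1, 5.2, 324, 5.1, 176, 57.1)),
                          fort = t(c(10.9, 7.0, 725, 8.8, 310, 103.3)),
                          suppl = t(c(70.9, 7.0, 60785, 8.8, 710, 103.3))),
    ghana_rural_pl = list(diet = t(c(22, 6, 1663, 3.4, 71, 9.5)),
                          fort = t(c(21.5, 6.4, 1663, 3.4, 71, 34.6)),
                          suppl = t(c(81.5, 6.4, 61723, 3.4, 471, 34.6)))
  )
}

#' Mandatory fortification programs per country
#'
#' Benin: salt iodation at 35 mg potassium iodate/kg (midpoint of the
#' regulated 30-40 range); vegetable oil at 50 IU retinyl palmitate/g; wheat
#' flour with ferrous fumarate 60 g/t, zinc oxide 55 g/t, niacin 36.18 g/t,
#' folic acid 2.6 g/t plus untracked B vitamins. Ghana: salt at 15 ppm
#' potassium iodate; oil at 10 mg retinyl palmitate/kg; wheat flour with
#' folic acid 2.08, ferrous fumarate 58.50, niacinamide 59.00, zinc oxide
#' 28.30 and retinyl palmitate 2.00 mg/kg plus untracked B vitamins. Flour
#' iron/zinc levels are read as elemental mass (`elemental_equivalent =
#' TRUE`), the reading that minimizes calibration residuals against the
#' published fortified rows; the choice is recorded in the fixture manifest.
#'
#' @param country `"benin"` or `"ghana"`.
#' @return Named list of `fortification_spec`s: `salt`, `oil`, `flour`.
#' @export
fixture_fortification_programs <- function(country = c("benin", "ghana")) {
  country <- match.arg(country)
  a <- function(compound, level, unit) list(compound = compound,
                                            level = level, unit = unit)
  if (country == "benin") {
    list(
      salt = fortification_spec("salt",
        list(a("potassium_iodate", 35, "mg/kg")), name = "fortify_salt"),
      oil = fortification_spec("veg_oil",
        list(a("retinyl_palmitate", 50, "IU/g")), name = "fortify_oil"),
      flour = fortification_spec("wheat_flour_products",
        list(a("ferrous_fumarate", 60, "g/t"), a("zinc_oxide", 55, "g/t"),
             a("thiamine", 2.79, "g/t"), a("riboflavin", 2.79, "g/t"),
             a("niacin", 36.18, "g/t"), a("pyridoxine", 3.13, "g/t"),
             a("cyanocobalamin", 0.02, "g/t"), a("folic_acid", 2.6, "g/t")),
        elemental_equivalent = TRUE, name = "fortify_flour"))
  } else {
    list(
      salt = fortification_spec("salt",
        list(a("potassium_iodate", 15, "ppm")), name = "fortify_salt"),
      oil = fortification_spec("veg_oil",
        list(a("retinyl_palmitate", 10, "mg/kg")), name = "fortify_oil"),
      flour = fortification_spec("wheat_flour_products",
        list(a("cyanocobalamin", 0.01, "mg/kg"), a("folic_acid", 2.08, "mg/kg"),
             a("ferrous_fumarate", 58.50, "mg/kg"),
             a("niacinamide", 59.00, "mg/kg"), a("riboflavin", 4.50, "mg/kg"),
             a("thiamine", 8.40, "mg/kg"),
             a("retinyl_palmitate", 2.00, "mg/kg"),
             a("zinc_oxide", 28.30, "mg/kg")),
        elemental_equivalent = TRUE, name = "fortify_flour"))
  }
}

#' Reference values packaged with the Benin/Ghana fixtures
#'
#' EAR/RNI/UL per nutrient for NPNL and PL women, back-calculated from the
#' published percentage cells where the source tables are unavailable or the
#' narrative contradicts them, and tagged accordingly. Notable entries: iron
#' RNI 58.8 mg (5% bioavailability) with the IoM UL of 45 mg; zinc RNI
#' 4.9 mg (the tables' cells back-calculate to the moderate-bioavailability
#' value, not the stated 15%/9.8 mg); vitamin A UL 3000 µg RAE; NPNL iodine
#' UL 1100 µg (the stated 30 µg/kg x 55 kg rule gives 1650, which no
#' published cell supports); PL iodine UL 2600 µg = 40 µg/kg x 65 kg; no UL
#' assessed for zinc in PL women. The registry is data-driven so official
#' WHO/IoM values can be swapped in.
#'
#' @return A `reference_set`.
#' @export
fixture_reference_set <- function() {
  df <- rbind(
    data.frame(nutrient = NUTRIENTS, group = "npnl",
               ear = c(29.4, 4.1, 357, 11, 320, 107),
               rni = c(58.8, 4.9, 500, 14.1, 400, 150),
               ul = c(45, 45, 3000, 35, 1000, 1100),
               bioavailability = c("5%", "moderate", NA, NA, NA, NA),
               source = c("WHO/IoM-UL", "back-calculated", "WHO",
                          "back-calculated", "WHO", "back-calculated"),
               stringsAsFactors = FALSE),
    data.frame(nutrient = NUTRIENTS, group = "pl",
               ear = c(40, 5.8, 572, 14.1, 480, 143),
               rni = c(30, 7.0, 800, 18, 600, 200),
               ul = c(45, NA, 3000, 35, 1000, 2600),
               bioavailability = c("5%", "moderate", NA, NA, NA, NA),
               source = c("back-calculated", "back-calculated",
                          "back-calculated", "back-calculated",
                          "back-calculated", "WHO-rule-40ug/kg"),
               stringsAsFactors = FALSE))
  reference_set(df)
}

# fixture food compositions shared across cells (per 100 g)
fixture_food_library <- function() {
  nv <- function(...) nutrient_vector(..., basis = "per_100g")
  list(
    food_item("salt", "iodizable salt", "raw", nv(),
              tags = "fortification-vehicle"),
    food_item("veg_oil", "refined vegetable oil", "raw", nv(),
              tags = "fortification-vehicle"),
    food_item("wheat_flour_products", "wheat-flour foods (bread, doughnut)",
              "cooked", nv(), tags = c("fortification-vehicle", "staple")),
    food_item("maize_porridge", "maize porridge", "cooked",
              nv(iron = 0.3, zinc = 0.2, niacin = 0.5, folate = 10),
              tags = "staple"),
    food_item("snack_set", "usual snacks (fried yam, orange, groundnut, melon)",
              "cooked",
              nv(iron = 1.2, zinc = 0.2, vitamin_a = 40, niacin = 4.2,
                 folate = 26), tags = "snack"),
    # fried orange sweet potato: same matrix as the snack set, vitamin A at
    # 55 ppm beta-carotene = 4.2 ug RE/g (crop-specific published density)
    food_item("fried_sweet_potato", "fried orange sweet potato", "cooked",
              nv(iron = 1.2, zinc = 0.2, vitamin_a = 420, niacin = 4.2,
                 folate = 26), tags = "snack"),
    food_item("red_palm_oil", "red palm oil", "raw",
              nv(vitamin_a = 5715), tags = "mn-rich"),
    food_item("mango", "mango", "raw",
              nv(iron = 0.2, zinc = 0.1, vitamin_a = 150, niacin = 0.7,
                 folate = 43), tags = "mn-rich"),
    food_item("fried_tilapia", "fried tilapia", "cooked",
              nv(iron = 2.9, zinc = 1.45, vitamin_a = 79, niacin = 3.55,
                 folate = 3.9), tags = "mn-rich"),
    # voluntary-fortified milk biscuit; composition back-calculated from the
    # published 40 g-portion deltas (folate 1321.80 ug / 40 g = 3304.5 / 100 g)
    food_item("fortified_biscuit", "voluntary-fortified milk biscuit", "cooked",
              nv(iron = 346.25, zinc = 14.75, vitamin_a = 1847.5,
                 niacin = 86.75, folate = 3304.5), tags = "mn-rich")
  )
}

# per-gram added-nutrient density of a fortification spec, canonical units
fortification_density_per_g <- function(f) {
  as.numeric(fortification_added_per_100g(f)) / 100
}

#' Back-calculate vehicle masses from published intake rows
#'
#' Given a cell's basal and fortified daily-intake rows and the country's
#' fortification levels, solves for the daily vehicle masses: salt from the
#' iodine delta, wheat flour from the folate delta (urban only; flour is not
#' consumed rurally), oil from the remaining vitamin A delta after the flour
#' contribution. The flour mass is cross-checked on iron, zinc and niacin and
#' the deviations of the recomputed fortified row from the published one are
#' returned as residuals (nutrient units).
#'
#' @param diet_row,fort_row Named numeric vectors over the six nutrients
#'   (daily intake, canonical units).
#' @param country `"benin"` or `"ghana"`.
#' @param setting `"urban"` or `"rural"`.
#' @return List with `masses` (g/day: salt, oil, flour) and `residuals`
#'   (published fortified row minus recomputed row).
#' @export
calibrate_vehicle_masses <- function(diet_row, fort_row, country, setting) {
  stopifnot(setting %in% c("urban", "rural"))
  progs <- fixture_fortification_programs(country)
  d_salt <- fortification_density_per_g(progs$salt)
  d_oil <- fortification_density_per_g(progs$oil)
  d_flour <- fortification_density_per_g(progs$flour)
  names(d_salt) <- names(d_oil) <- names(d_flour) <- NUTRIENTS
  delta <- fort_row[NUTRIENTS] - diet_row[NUTRIENTS]

  solve_mass <- function(delta_n, dens) {
    if (delta_n <= 0) return(0)
    if (dens == 0) stop("calibration error: nonzero delta with zero density",
                        call. = FALSE)
    delta_n / dens
  }
  flour_g <- if (setting == "urban")
    solve_mass(delta[["folate"]], d_flour[["folate"]]) else 0
  salt_g <- solve_mass(delta[["iodine"]], d_salt[["iodine"]])
  va_left <- max(delta[["vitamin_a"]] - flour_g * d_flour[["vitamin_a"]], 0)
  oil_g <- solve_mass(va_left, d_oil[["vitamin_a"]])

  recomputed <- diet_row[NUTRIENTS] + flour_g * d_flour + salt_g * d_salt +
    oil_g * d_oil
  list(masses = c(salt = unname(salt_g), oil = unname(oil_g),
                  flour = unname(flour_g)),
       residuals = fort_row[NUTRIENTS] - recomputed)
}

# grams/day of basal vehicles other than the calibrated three
fixture_side_masses <- function(country, setting) {
  if (country == "ghana") {
    c(maize_porridge = if (setting == "urban") 100 else 150, snack_set = 50)
  } else {
    c(maize_porridge = 0, snack_set = 0)
  }
}

build_cell_table <- function(cid, diet_row, side) {
  lib <- fixture_food_library()
  # composite basal food absorbs everything the named vehicles don't carry,
  # so the basal scenario reproduces the published Diet row exactly
  total_composite_g <- if (grepl("urban", cid)) 1000 else 1100
  contrib <- stats::setNames(numeric(length(NUTRIENTS)), NUTRIENTS)
  for (f in lib) {
    g <- side[f$food_id]
    if (!is.na(g) && g > 0) {
      contrib <- contrib + as.numeric(f$composition) * g / 100
    }
  }
  comp_day <- diet_row[NUTRIENTS] - contrib
  if (any(comp_day < -1e-9)) {
    stop("composite composition would be negative for cell ", cid,
         call. = FALSE)
  }
  comp_day[comp_day < 0] <- 0
  composite <- food_item(
    "basal_composite", paste0("calibrated composite basal diet (", cid, ")"),
    "cooked",
    as_nutrient_vector(comp_day / total_composite_g * 100, "per_100g"),
    tags = c("staple", "synthetic-composite"))
  list(table = composition_table(c(lib, list(composite)),
                                 provenance = paste0("fixture:", cid)),
       composite_g = total_composite_g)
}

build_cell_scenario <- function(country, setting, group, masses, side,
                                composite_g) {
  half <- function(x) x / 2
  ing <- function(...) {
    df <- data.frame(...)
    df[df$grams > 0, , drop = FALSE]
  }
  dishes <- list()
  if (setting == "urban") {
    # 6 meals: breakfast, morning meal, lunch, snack, dinner, after-dinner
    split6 <- c(150, 100, 300, 100, 250, 100)  # composite g per meal
    dishes <- list(
      dish("breakfast_plate", ing(
        food_id = c("basal_composite", "wheat_flour_products",
                    "maize_porridge"),
        grams = c(split6[1], masses[["flour"]], side[["maize_porridge"]]))),
      dish("morning_plate", ing(food_id = "basal_composite",
                                grams = split6[2])),
      dish("lunch_plate", ing(
        food_id = c("basal_composite", "veg_oil", "salt"),
        grams = c(split6[3], half(masses[["oil"]]), half(masses[["salt"]])))),
      dish("snack_plate", ing(
        food_id = c("basal_composite", "snack_set"),
        grams = c(split6[4], side[["snack_set"]] / 2))),
      dish("dinner_plate", ing(
        food_id = c("basal_composite", "veg_oil", "salt"),
        grams = c(split6[5], half(masses[["oil"]]), half(masses[["salt"]])))),
      dish("evening_snack_plate", ing(
        food_id = c("basal_composite", "snack_set"),
        grams = c(split6[6], side[["snack_set"]] / 2)))
    )
    meals <- lapply(seq_along(dishes), function(i)
      list(label = c("breakfast", "morning_meal", "lunch", "snack", "dinner",
                     "after_dinner_snack")[i],
           dishes = data.frame(dish_id = dishes[[i]]$dish_id, multiplier = 1,
                               stringsAsFactors = FALSE)))
  } else {
    # 4 meals; larger rural portions are encoded as portion multipliers on a
    # shared composite portion, not duplicated dishes
    base_portion <- 250
    mult <- c(1.0, 1.4, 0.8, 1.2) * composite_g / (base_portion * 4.4)
    dishes <- list(dish("composite_portion",
                        ing(food_id = "basal_composite", grams = base_portion)))
    extras <- list(
      breakfast = ing(food_id = "maize_porridge",
                      grams = side[["maize_porridge"]]),
      lunch = ing(food_id = c("veg_oil", "salt"),
                  grams = c(half(masses[["oil"]]), half(masses[["salt"]]))),
      afternoon = ing(food_id = "snack_set", grams = side[["snack_set"]]),
      dinner = ing(food_id = c("veg_oil", "salt"),
                   grams = c(half(masses[["oil"]]), half(masses[["salt"]]))))
    meals <- list()
    for (i in seq_along(extras)) {
      label <- names(extras)[i]
      md <- data.frame(dish_id = "composite_portion", multiplier = mult[i],
                       stringsAsFactors = FALSE)
      if (nrow(extras[[i]])) {
        did <- paste0(label, "_extra")
        dishes[[length(dishes) + 1]] <- dish(did, extras[[i]])
        md <- rbind(md, data.frame(dish_id = did, multiplier = 1,
                                   stringsAsFactors = FALSE))
      }
      meals[[length(meals) + 1]] <- list(label = label, dishes = md)
    }
  }
  diet_scenario(country = country, setting = setting,
                group = population_group(group), plan = meal_plan(meals),
                dishes = dishes)
}

# supplement specs used by the fixtures
ifa_supplement <- function() {
  supplement_spec("ifa", nutrient_vector(iron = 60, folate = 400,
                                         basis = "per_day"),
                  schedule = "daily")
}

vas_supplement <- function() {
  supplement_spec("vas",
                  nutrient_vector(vitamin_a = to_ug_rae("retinol_iu", 200000),
                                  basis = "per_day"),
                  schedule = "single_high_dose")
}

biofortified_maize_spec <- function() {
  # basal porridge matrix plus 6 ppm beta-carotene = 0.5 ug RE/g = 50 / 100 g
  repl <- nutrient_vector(iron = 0.3, zinc = 0.2, vitamin_a = 50,
                          niacin = 0.5, folate = 10, basis = "per_100g")
  biofortification_spec("maize_porridge", repl, name = "biofortify_maize")
}

osp_snack_swap <- function() {
  food_swap_spec("replace", old_id = "snack_set",
                 new_id = "fried_sweet_potato", name = "swap_osp_snack")
}

#' Build one calibrated Benin/Ghana fixture cell
#'
#' Deterministically constructs the diet scenario, composition table,
#' intervention bundles and reference set for one country x setting x group
#' cell. Bundles follow the published intervention-availability matrix:
#' salt and oil fortification everywhere; wheat-flour fortification in urban
#' cells only; maize/orange-sweet-potato biofortification in Ghana only;
#' iron-folic-acid supplementation for PL women only; high-dose post-partum
#' vitamin A (VAS) for PL women in Ghana only; fried tilapia for NPNL women
#' and the voluntary-fortified biscuit for PL women; mango and the red palm
#' oil swap everywhere.
#'
#' @param country `"benin"` or `"ghana"`.
#' @param setting `"urban"` or `"rural"`.
#' @param group `"npnl"` or `"pl"`.
#' @return A list with elements `scenario` (`diet_scenario`), `table`
#'   (`composition_table`), `bundles` (named list of `scenario_bundle`s),
#'   `refs` (`reference_set`) and `manifest` (calibration masses, residuals,
#'   flags).
#' @export
build_fixture <- function(country = c("benin", "ghana"),
                          setting = c("urban", "rural"),
                          group = c("npnl", "pl")) {
  country <- match.arg(country)
  setting <- match.arg(setting)
  group <- match.arg(group)
  cid <- cell_id(country, setting, group)
  targets <- fixture_targets()[[cid]]
  if (is.null(targets)) stop("invalid fixture cell: ", cid, call. = FALSE)

  cal <- calibrate_vehicle_masses(targets$diet, targets$fort, country, setting)
  side <- fixture_side_masses(country, setting)
  tb <- build_cell_table(cid, targets$diet, side)
  scenario <- build_cell_scenario(country, setting, group, cal$masses, side,
                                  tb$composite_g)

  progs <- fixture_fortification_programs(country)
  fort_layers <- list(progs$salt, progs$oil)
  if (setting == "urban") fort_layers <- c(fort_layers, list(progs$flour))
  biofort_layers <- if (country == "ghana")
    list(biofortified_maize_spec(), osp_snack_swap()) else list()
  suppl_layers <- if (group == "pl") {
    c(list(ifa_supplement()),
      if (country == "ghana") list(vas_supplement()) else list())
  } else list()
  mnrich_layers <- c(
    list(food_swap_spec("add", food_id = "mango", grams = 100,
                        name = "add_mango")),
    if (group == "npnl")
      list(food_swap_spec("add", food_id = "fried_tilapia", grams = 76,
                          name = "add_tilapia"))
    else
      list(food_swap_spec("add", food_id = "fortified_biscuit", grams = 40,
                          name = "add_biscuit")))
  rpo_swap <- food_swap_spec("replace", old_id = "veg_oil",
                             new_id = "red_palm_oil", name = "swap_red_palm_oil")

  bundles <- list(
    diet = scenario_bundle(scenario, list(), label = "diet"),
    diet_fortification = scenario_bundle(scenario, fort_layers,
                                         label = "diet_fortification"))
  if (country == "ghana") {
    bundles$diet_fortification_biofortification <- scenario_bundle(
      scenario, c(fort_layers, biofort_layers),
      label = "diet_fortification_biofortification")
  }
  if (group == "pl") {
    bundles$diet_fortification_supplementation <- scenario_bundle(
      scenario, c(fort_layers, suppl_layers),
      label = "diet_fortification_supplementation")
  }
  if (country == "ghana" && group == "pl") {
    bundles$diet_fortification_ifa_biofortification <- scenario_bundle(
      scenario, c(fort_layers, biofort_layers, list(ifa_supplement())),
      label = "diet_fortification_ifa_biofortification")
  }
  no_vas <- Filter(function(l) !identical(l$name, "vas"), suppl_layers)
  bundles$all_mn_rich <- scenario_bundle(
    scenario, c(fort_layers, biofort_layers, no_vas, mnrich_layers),
    label = "all_mn_rich")
  fort_no_oil <- Filter(function(l) !identical(l$name, "fortify_oil"),
                        fort_layers)
  bundles$all_red_palm_oil <- scenario_bundle(
    scenario,
    c(fort_no_oil, biofort_layers, no_vas, mnrich_layers, list(rpo_swap)),
    label = "all_red_palm_oil")

  manifest <- list(
    cell = cid,
    vehicle_masses_g = as.list(cal$masses),
    side_masses_g = as.list(side),
    composite_g = tb$composite_g,
    fortified_row_residuals = as.list(round(cal$residuals, 6)),
    fortified_row_consistent = all(abs(cal$residuals) <
                                     pmax(0.25, 0.02 * targets$fort)),
    flour_levels_read_as = "elemental",
    supplementation_row_residuals = if (!is.null(targets$suppl)) {
      ifa <- as.numeric(ifa_supplement()$doses)
      vas <- if (country == "ghana") as.numeric(vas_supplement()$doses) else
        numeric(length(NUTRIENTS))
      expected <- targets$fort + ifa + vas
      as.list(round(targets$suppl - expected, 6))
    } else NULL,
    non_target_rows = paste(
      "biofortification and MN-rich/red-palm-oil rows are not calibration",
      "targets: the published cells for those rows are mutually inconsistent",
      "across settings"),
    targets = lapply(targets, as.list)
  )
  list(scenario = scenario, table = tb$table, bundles = bundles,
       refs = fixture_reference_set(), manifest = manifest)
}

#' Emit the packaged fixture files to a directory
#'
#' Writes, per cell, `composition_<cell>.csv` and `scenario_<cell>.json`,
#' plus a shared `references.csv` and a `manifest.json` recording calibrated
#' vehicle masses, residuals against the published rows, and the
#' compound-vs-elemental reading chosen for wheat flour.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixture_files <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cells <- fixture_cells()
  manifests <- list()
  paths <- character()
  for (i in seq_len(nrow(cells))) {
    fx <- build_fixture(cells$country[i], cells$setting[i], cells$group[i])
    cid <- fx$manifest$cell
    p1 <- file.path(dir, paste0("composition_", cid, ".csv"))
    write_composition_table(fx$table, p1)
    p2 <- file.path(dir, paste0("scenario_", cid, ".json"))
    write_scenario(fx$scenario, p2)
    manifests[[cid]] <- fx$manifest
    paths <- c(paths, p1, p2)
  }
  p3 <- file.path(dir, "references.csv")
  write_reference_set(fixture_reference_set(), p3)
  p4 <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifests, p4, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, p3, p4))
}

# --- randomized synthetic scenarios ------------------------------------------

#' Configuration for the synthetic scenario generator
#'
#' @param seed RNG seed; the same seed always yields identical output.
#' @param n_foods,n_dishes,n_meals,n_layers Problem sizes.
#' @param density_max Per-nutrient maximum composition density (per 100 g);
#'   canonical units.
#' @param mass_range Ingredient mass range, grams.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = FIXTURE_SEED, n_foods = 8, n_dishes = 5,
                             n_meals = 4, n_layers = 3,
                             density_max = c(iron = 20, zinc = 15,
                                             vitamin_a = 500, niacin = 20,
                                             folate = 400, iodine = 50),
                             mass_range = c(5, 300)) {
  stopifnot(n_foods >= 2, n_dishes >= 1, n_meals >= 1, n_layers >= 0,
            all(density_max >= 0), mass_range[1] > 0,
            mass_range[2] >= mass_range[1])
  structure(list(seed = as.integer(seed), n_foods = n_foods,
                 n_dishes = n_dishes, n_meals = n_meals, n_layers = n_layers,
                 density_max = density_max, mass_range = mass_range),
            class = "synthetic_config")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a random scenario bundle and composition table
#'
#' Seed-deterministic generator used by the property-based test suites:
#' random foods with densities within configured ranges, random dishes and
#' meal plans, and a random mix of intervention layers (fortification of a
#' random vehicle, biofortification, supplements, add/replace food swaps).
#'
#' @param cfg A `synthetic_config`.
#' @return A list with elements `bundle` (`scenario_bundle`) and `table`
#'   (`composition_table`).
#' @export
random_scenario <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_local_seed(cfg$seed, {
    food_ids <- sprintf("food%02d", seq_len(cfg$n_foods))
    foods <- lapply(food_ids, function(fid) {
      dens <- stats::runif(length(NUTRIENTS)) * cfg$density_max
      food_item(fid, composition = as_nutrient_vector(dens, "per_100g"))
    })
    # extra foods available for swaps but absent from the basal diet
    swap_ids <- c("swapfood_a", "swapfood_b")
    foods <- c(foods, lapply(swap_ids, function(fid) {
      dens <- stats::runif(length(NUTRIENTS)) * cfg$density_max
      food_item(fid, composition = as_nutrient_vector(dens, "per_100g"))
    }))
    tab <- composition_table(foods, provenance = "synthetic")

    dish_ids <- sprintf("dish%02d", seq_len(cfg$n_dishes))
    dishes <- lapply(dish_ids, function(did) {
      k <- sample(1:3, 1)
      dish(did, data.frame(
        food_id = sample(food_ids, k),
        grams = stats::runif(k, cfg$mass_range[1], cfg$mass_range[2]),
        stringsAsFactors = FALSE))
    })
    meals <- lapply(seq_len(cfg$n_meals), function(i) {
      k <- sample(1:2, 1)
      list(label = paste0("meal", i),
           dishes = data.frame(dish_id = sample(dish_ids, k),
                               multiplier = stats::runif(k, 0.5, 2),
                               stringsAsFactors = FALSE))
    })
    scen <- diet_scenario(country = sample(c("benin", "ghana"), 1),
                          setting = sample(c("urban", "rural"), 1),
                          group = population_group(sample(c("npnl", "pl"), 1)),
                          plan = meal_plan(meals), dishes = dishes)

    mk_layer <- function(i) {
      kind <- sample(c("fortification", "biofortification", "supplement",
                       "swap_add", "swap_replace"), 1)
      switch(kind,
        fortification = {
          compound <- sample(c("potassium_iodate", "retinyl_palmitate",
                               "ferrous_fumarate", "zinc_oxide", "folic_acid",
                               "niacinamide"), 1)
          fortification_spec(sample(food_ids, 1),
            list(list(compound = compound,
                      level = stats::runif(1, 0, 60), unit = "mg/kg")),
            elemental_equivalent = sample(c(TRUE, FALSE), 1),
            name = paste0("L", i, "_fort"))
        },
        biofortification = {
          dens <- stats::runif(length(NUTRIENTS)) * cfg$density_max
          biofortification_spec(sample(food_ids, 1),
                                as_nutrient_vector(dens, "per_100g"),
                                name = paste0("L", i, "_biofort"))
        },
        supplement = {
          dose <- stats::runif(length(NUTRIENTS)) * c(60, 15, 800, 30, 400, 150)
          supplement_spec(paste0("L", i, "_suppl"),
                          as_nutrient_vector(dose, "per_day"))
        },
        swap_add = food_swap_spec("add", food_id = sample(swap_ids, 1),
                                  grams = stats::runif(1, 10, 150),
                                  name = paste0("L", i, "_add")),
        swap_replace = food_swap_spec("replace",
                                      old_id = sample(food_ids, 1),
                                      new_id = sample(swap_ids, 1),
                                      name = paste0("L", i, "_swap")))
    }
    layers <- list()
    if (cfg$n_layers > 0) {
      repeat {
        layers <- lapply(seq_len(cfg$n_layers), mk_layer)
        veh <- vapply(layers, function(l)
          if (inherits(l, "fortification_spec")) l$vehicle else NA_character_,
          character(1))
        if (!anyDuplicated(veh[!is.na(veh)])) break
      }
    }
    list(bundle = scenario_bundle(scen, layers,
                                  label = paste0("synthetic_", cfg$seed)),
         table = tab)
  })
}

# --- independent brute-force oracle ------------------------------------------

#' Brute-force daily intake oracle
#'
#' An independent re-implementation of scenario resolution used to
#' cross-check [compose_bundle()] and [daily_intake()]: it transforms a plain
#' copy of the food map and dish list with its own arithmetic (no calls into
#' the table/diet/intervention application code) and totals intake by a naive
#' triple loop over meals x dishes x ingredients, plus supplements. Unit
#' conversion primitives ([to_ug_rae()], [iodate_to_iodine()]) are shared;
#' everything above them is re-derived.
#'
#' @param bundle A `scenario_bundle`.
#' @param table A `composition_table`.
#' @return A per-day `nutrient_vector`.
#' @export
oracle_intake <- function(bundle, table) {
  stopifnot(inherits(bundle, "scenario_bundle"),
            inherits(table, "composition_table"))
  # plain food map: id -> numeric density vector per 100 g
  comp <- lapply(table$foods, function(f) as.numeric(f$composition))
  dishes <- lapply(bundle$base$dishes, function(d) d$ingredients)
  meals <- lapply(bundle$base$plan$meals, function(m) m$dishes)
  extra <- list()  # (food_id, grams) additions
  supp <- numeric(length(NUTRIENTS))

  ord <- order(vapply(bundle$layers, layer_type_order, integer(1)))
  for (l in bundle$layers[ord]) {
    if (inherits(l, "biofortification_spec")) {
      if (is.null(comp[[l$target]])) stop("oracle: unknown food ", l$target)
      comp[[l$target]] <- as.numeric(l$replacement)
    } else if (inherits(l, "fortification_spec")) {
      if (is.null(comp[[l$vehicle]])) stop("oracle: unknown food ", l$vehicle)
      add <- numeric(length(NUTRIENTS))
      names(add) <- NUTRIENTS
      for (a in l$additions) {
        nut <- FORTIFICANTS[[a$compound]]$nutrient
        if (is.na(nut)) next
        per_g <- if (a$unit == "IU/g") {
          to_ug_rae("retinol_iu", a$level)
        } else if (nut == "iodine") {
          if (l$elemental_equivalent) a$level else
            iodate_to_iodine(IODATE_COMPOUND[[a$compound]], a$level)
        } else if (nut == "vitamin_a") {
          to_ug_rae("retinyl_palmitate_mass", a$level) / 1000
        } else if (nut == "folate") {
          a$level * if (l$elemental_equivalent) 1 else
            FORTIFICANTS[[a$compound]]$fraction
        } else {
          (a$level * if (l$elemental_equivalent) 1 else
            FORTIFICANTS[[a$compound]]$fraction) / 1000
        }
        add[nut] <- add[nut] + per_g * 100
      }
      comp[[l$vehicle]] <- comp[[l$vehicle]] + unname(add[NUTRIENTS])
    } else if (inherits(l, "food_swap_spec")) {
      if (l$action == "add") {
        extra[[length(extra) + 1]] <- list(food_id = l$food_id,
                                           grams = l$grams)
      } else {
        for (did in names(dishes)) {
          m <- dishes[[did]]$food_id == l$old_id
          dishes[[did]]$food_id[m] <- l$new_id
        }
      }
    } else if (inherits(l, "supplement_spec")) {
      supp <- supp + as.numeric(l$doses)
    }
  }

  total <- numeric(length(NUTRIENTS))
  for (m in meals) {
    for (j in seq_len(nrow(m))) {
      ing <- dishes[[m$dish_id[j]]]
      for (k in seq_len(nrow(ing))) {
        dens <- comp[[ing$food_id[k]]]
        if (is.null(dens)) stop("oracle: unknown food ", ing$food_id[k])
        total <- total + m$multiplier[j] * ing$grams[k] * dens / 100
      }
    }
  }
  for (e in extra) {
    dens <- comp[[e$food_id]]
    if (is.null(dens)) stop("oracle: unknown food ", e$food_id)
    total <- total + e$grams * dens / 100
  }
  as_nutrient_vector(total + supp, "per_day")
}
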