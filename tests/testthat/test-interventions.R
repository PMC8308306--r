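# intervention layers and bundle composition

test_that("apply_fortification adds converted nutrient mass to the vehicle", {
  tab <- tiny_table()
  # 50 IU retinyl palmitate per g oil -> +15 ug RAE/g = +1500 ug RE / 100 g
  f <- fortification_spec("oil", list(
    list(compound = "retinyl_palmitate", level = 50, unit = "IU/g")))
  tab2 <- apply_fortification(tab, f)
  expect_equal(as.numeric(ct_get(tab2, "oil")$composition[["vitamin_a"]]), 1500)
  # original table untouched; other foods untouched
  expect_equal(as.numeric(ct_get(tab, "oil")$composition[["vitamin_a"]]), 0)
  expect_equal(as.numeric(ct_get(tab2, "riceA")$composition),
               as.numeric(ct_get(tab, "riceA")$composition))
  # idempotent
  tab3 <- apply_fortification(tab2, f)
  expect_equal(as.numeric(ct_get(tab3, "oil")$composition),
               as.numeric(ct_get(tab2, "oil")$composition))

  # folic acid 2.6 g/t -> +260 ug folate / 100 g
  f2 <- fortification_spec("riceA", list(
    list(compound = "folic_acid", level = 2.6, unit = "g/t")))
  tab4 <- apply_fortification(tab, f2)
  expect_equal(as.numeric(ct_get(tab4, "riceA")$composition[["folate"]]) -
                 as.numeric(ct_get(tab, "riceA")$composition[["folate"]]), 260)

  # compound vs elemental reading for ferrous fumarate (fraction 0.328)
  lvl <- list(list(compound = "ferrous_fumarate", level = 60, unit = "g/t"))
  cmp <- apply_fortification(tab, fortification_spec("oil", lvl))
  elm <- apply_fortification(tab, fortification_spec(
    "oil", lvl, elemental_equivalent = TRUE))
  expect_equal(as.numeric(ct_get(cmp, "oil")$composition[["iron"]]),
               60 * 0.328 / 10)
  expect_equal(as.numeric(ct_get(elm, "oil")$composition[["iron"]]), 6)

  # level 0 leaves the composition unchanged
  z <- apply_fortification(tab, fortification_spec("oil", list(
    list(compound = "folic_acid", level = 0, unit = "mg/kg"))))
  expect_equal(as.numeric(ct_get(z, "oil")$composition),
               as.numeric(ct_get(tab, "oil")$composition))

  expect_error(apply_fortification(tab, fortification_spec("ghost", list())),
               "unknown food_id")
  expect_error(fortification_spec("oil", list(
    list(compound = "unobtainium", level = 1, unit = "mg/kg"))),
    "unknown fortificant")
})

test_that("apply_biofortification replaces composition wholesale, idempotently", {
  tab <- tiny_table()
  repl <- nutrient_vector(iron = 1.2, zinc = 0.8, vitamin_a = 50,
                          niacin = 1.5, folate = 8, basis = "per_100g")
  b <- biofortification_spec("riceA", repl)
  t1 <- apply_biofortification(tab, b)
  t2 <- apply_biofortification(t1, b)
  expect_equal(as.numeric(ct_get(t1, "riceA")$composition), as.numeric(repl))
  expect_equal(as.numeric(ct_get(t2, "riceA")$composition),
               as.numeric(ct_get(t1, "riceA")$composition))
  # replacement identical to original leaves the table unchanged
  same <- biofortification_spec("oil", ct_get(tab, "oil")$composition)
  expect_equal(as.numeric(ct_get(apply_biofortification(tab, same),
                                 "oil")$composition),
               as.numeric(ct_get(tab, "oil")$composition))
  expect_error(apply_biofortification(tab, biofortification_spec(
    "ghost", repl)), "unknown food_id")
})

test_that("apply_supplement is element-wise addition", {
  base <- nutrient_vector(iron = 10.9, folate = 749, basis = "per_day")
  ifa <- supplement_spec("ifa", nutrient_vector(iron = 60, folate = 400,
                                                basis = "per_day"))
  out <- apply_supplement(base, ifa)
  expect_equal(as.numeric(out[["iron"]]), 70.9)
  expect_equal(as.numeric(out[["folate"]]), 1149)
  none <- supplement_spec("none", nutrient_vector(basis = "per_day"))
  expect_equal(as.numeric(apply_supplement(base, none)), as.numeric(base))
})

test_that("compose_bundle: no layers, ordering, contributions", {
  tab <- tiny_table()
  s <- tiny_scenario()
  b0 <- scenario_bundle(s, list(), label = "basal")
  r0 <- compose_bundle(b0, tab)
  expect_equal(as.numeric(r0$total), as.numeric(daily_intake(s, tab)))
  expect_length(r0$contributions, 0)

  layers <- list(
    fortification_spec("oil", list(
      list(compound = "retinyl_palmitate", level = 50, unit = "IU/g")),
      name = "oil_fort"),
    supplement_spec("ifa", nutrient_vector(iron = 60, folate = 400,
                                           basis = "per_day")),
    food_swap_spec("add", food_id = "fishB", grams = 76, name = "add_fish"))
  b <- scenario_bundle(s, layers, label = "combo")
  r <- compose_bundle(b, tab)
  # contributions sum with base to the total
  expect_equal(as.numeric(r$base) +
                 Reduce(`+`, lapply(r$contributions, as.numeric)),
               as.numeric(r$total), tolerance = 1e-12)
  # additive layers have non-negative contributions
  for (cc in r$contributions) expect_true(all(as.numeric(cc) >= -1e-12))
  # oil fortification contributes 30 g x 15 ug RAE/g
  expect_equal(as.numeric(r$contributions$oil_fort[["vitamin_a"]]), 450)

  # two fortifications on one vehicle conflict
  expect_error(scenario_bundle(s, list(layers[[1]], fortification_spec(
    "oil", list(list(compound = "folic_acid", level = 1, unit = "mg/kg"))))),
    "conflicting layers")
})

test_that("layers on disjoint foods commute", {
  tab <- tiny_table()
  s <- tiny_scenario()
  la <- fortification_spec("oil", list(
    list(compound = "retinyl_palmitate", level = 50, unit = "IU/g")),
    name = "A")
  lb <- fortification_spec("riceA", list(
    list(compound = "folic_acid", level = 2.6, unit = "g/t")), name = "B")
  r1 <- compose_bundle(scenario_bundle(s, list(la, lb)), tab)
  r2 <- compose_bundle(scenario_bundle(s, list(lb, la)), tab)
  expect_equal(as.numeric(r1$total), as.numeric(r2$total), tolerance = 1e-12)
})

test_that("monotonicity: adding additive layers never decreases any nutrient", {
  set.seed(42)
  for (i in 1:25) {
    rs <- random_scenario(synthetic_config(seed = 5000 + i, n_layers = 0))
    base <- compose_bundle(rs$bundle, rs$table)$total
    extra <- list(
      fortification_spec(sample(ct_ids(rs$table), 1), list(
        list(compound = "zinc_oxide", level = runif(1, 0, 80),
             unit = "mg/kg"))),
      supplement_spec("s", as_nutrient_vector(runif(6, 0, 50), "per_day")),
      food_swap_spec("add", food_id = sample(ct_ids(rs$table), 1),
                     grams = runif(1, 1, 200), name = "extra_add"))
    for (l in extra) {
      b2 <- scenario_bundle(rs$bundle$base, c(rs$bundle$layers, list(l)))
      tot <- compose_bundle(b2, rs$table)$total
      expect_true(all(as.numeric(tot) - as.numeric(base) >= -1e-9))
    }
  }
})
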