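# Small hand-built objects shared across test files.

tiny_table <- function() {
  composition_table(list(
    food_item("riceA", composition = nutrient_vector(
      iron = 1.2, zinc = 0.8, niacin = 1.5, folate = 8, basis = "per_100g")),
    food_item("oil", composition = nutrient_vector(basis = "per_100g"),
              tags = "fortification-vehicle"),
    food_item("fishB", composition = nutrient_vector(
      iron = 2.0, zinc = 1.0, vitamin_a = 30, niacin = 3.0, folate = 5,
      basis = "per_100g")),
    food_item("red_palm", composition = nutrient_vector(
      vitamin_a = 5715, basis = "per_100g"))
  ), provenance = "test")
}

tiny_scenario <- function(oil_g = 30) {
  d1 <- dish("d1", data.frame(food_id = c("riceA", "oil"),
                              grams = c(150, oil_g / 2)))
  d2 <- dish("d2", data.frame(food_id = c("riceA", "fishB", "oil"),
                              grams = c(100, 50, oil_g / 2)))
  diet_scenario(
    country = "benin", setting = "urban", group = population_group("npnl"),
    plan = meal_plan(list(
      list(label = "lunch", dishes = data.frame(dish_id = "d1",
                                                multiplier = 1)),
      list(label = "dinner", dishes = data.frame(dish_id = "d2",
                                                 multiplier = 1)))),
    dishes = list(d1, d2))
}

nv_num <- function(x) as.numeric(x)

ALL_CELLS <- expand.grid(country = c("benin", "ghana"),
                         setting = c("urban", "rural"),
                         group = c("npnl", "pl"), stringsAsFactors = FALSE)
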