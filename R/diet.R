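# Meal patterns, dishes and daily diet scenarios; flattening to ingredient
# masses and total daily micronutrient intake.

#' Create a dish
#'
#' A dish is a recipe: a list of (food_id, mass in grams as consumed).
#' Ingredient ids are resolved against the active composition table at
#' evaluation time, not at construction.
#'
#' @param dish_id Dish identifier.
#' @param ingredients Data frame with columns `food_id` (character) and
#'   `grams` (> 0).
#' @return An object of class `dish`.
#' @export
dish <- function(dish_id, ingredients) {
  stopifnot(is.character(dish_id), length(dish_id) == 1,
            is.data.frame(ingredients),
            all(c("food_id", "grams") %in% names(ingredients)))
  if (nrow(ingredients) && any(!is.finite(ingredients$grams) |
                               ingredients$grams <= 0)) {
    stop("ingredient masses must be positive", call. = FALSE)
  }
  structure(list(dish_id = dish_id,
                 ingredients = ingredients[, c("food_id", "grams")]),
            class = "dish")
}

#' Create a meal plan
#'
#' An ordered list of meals; each meal lists dishes with portion multipliers.
#' Urban patterns use 6 meals per day, rural patterns 4 meals with larger
#' portions (encoded through the multipliers, not duplicated dishes).
#'
#' @param meals A list; each element is `list(label =, dishes =)` where
#'   `dishes` is a data.frame with columns `dish_id` and `multiplier` (> 0).
#' @return An object of class `meal_plan`.
#' @export
meal_plan <- function(meals = list()) {
  for (m in meals) {
    stopifnot(is.list(m), !is.null(m$label), is.data.frame(m$dishes),
              all(c("dish_id", "multiplier") %in% names(m$dishes)))
    if (nrow(m$dishes) && any(!is.finite(m$dishes$multiplier) |
                              m$dishes$multiplier <= 0)) {
      stop("portion multipliers must be positive", call. = FALSE)
    }
  }
  structure(list(meals = meals), class = "meal_plan")
}

#' Population groups: NPNL and PL women
#'
#' Two reference groups of women of reproductive age: non-pregnant,
#' non-lactating (NPNL, assumed body weight 55 kg) and pregnant or lactating
#' (PL, assumed body weight 65 kg). Body weight feeds the iodine upper-limit
#' rule.
#'
#' @param id `"npnl"` or `"pl"`.
#' @param body_weight Assumed body weight in kg; defaults to 55 (NPNL) or
#'   65 (PL).
#' @return An object of class `population_group`.
#' @export
population_group <- function(id = c("npnl", "pl"), body_weight = NULL) {
  id <- match.arg(id)
  if (is.null(body_weight)) body_weight <- c(npnl = 55, pl = 65)[[id]]
  stopifnot(is.numeric(body_weight), body_weight > 0)
  structure(list(id = id, body_weight = body_weight),
            class = "population_group")
}

#' Create a diet scenario
#'
#' A single representative day of eating for one country x setting x group
#' cell: a meal plan over a registry of dishes.
#'
#' @param country `"benin"` or `"ghana"`.
#' @param setting `"urban"` or `"rural"`.
#' @param group A `population_group`.
#' @param plan A `meal_plan`; every `dish_id` it references must exist in
#'   `dishes`.
#' @param dishes A list of `dish` objects (the dish registry).
#' @return An object of class `diet_scenario`.
#' @export
diet_scenario <- function(country = c("benin", "ghana"),
                          setting = c("urban", "rural"),
                          group = population_group("npnl"),
                          plan = meal_plan(),
                          dishes = list()) {
  country <- match.arg(country)
  setting <- match.arg(setting)
  stopifnot(inherits(group, "population_group"), inherits(plan, "meal_plan"),
            is.list(dishes))
  ids <- vapply(dishes, function(d) {
    if (!inherits(d, "dish")) stop("dish registry entries must be dish objects",
                                   call. = FALSE)
    d$dish_id
  }, character(1))
  if (anyDuplicated(ids)) stop("duplicate dish_id in registry", call. = FALSE)
  names(dishes) <- ids
  for (m in plan$meals) {
    missing <- setdiff(m$dishes$dish_id, ids)
    if (length(missing)) {
      stop("meal '", m$label, "' references unknown dish: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(country = country, setting = setting, group = group,
                 plan = plan, dishes = dishes),
            class = "diet_scenario")
}

#' @export
print.diet_scenario <- function(x, ...) {
  cat("<diet_scenario ", x$country, "/", x$setting, "/", x$group$id, ": ",
      length(x$plan$meals), " meals, ", length(x$dishes), " dishes>\n",
      sep = "")
  invisible(x)
}

#' Flatten a diet scenario to daily ingredient masses
#'
#' Sums portion multiplier x ingredient mass over all meals and dishes,
#' yielding one row per distinct food, sorted by `food_id` for deterministic
#' output.
#'
#' @param s A `diet_scenario`.
#' @return Data frame with columns `food_id` and `grams` (g/day).
#' @export
resolve_daily_ingredients <- function(s) {
  stopifnot(inherits(s, "diet_scenario"))
  acc <- new.env(parent = emptyenv())
  for (m in s$plan$meals) {
    for (j in seq_len(nrow(m$dishes))) {
      did <- m$dishes$dish_id[j]
      d <- s$dishes[[did]]
      if (is.null(d)) stop("unresolved dish_id: ", did, call. = FALSE)
      mult <- m$dishes$multiplier[j]
      ing <- d$ingredients
      for (k in seq_len(nrow(ing))) {
        fid <- ing$food_id[k]
        prev <- if (is.null(acc[[fid]])) 0 else acc[[fid]]
        acc[[fid]] <- prev + mult * ing$grams[k]
      }
    }
  }
  ids <- sort(ls(acc))
  data.frame(food_id = ids,
             grams = vapply(ids, function(i) acc[[i]], numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Total daily micronutrient intake of a scenario
#'
#' Totals the micronutrient content of each individual food ingredient:
#' per nutrient, the sum over resolved ingredients of
#' grams x density per 100 g, plus an optional per-day supplement vector.
#'
#' @param s A `diet_scenario`.
#' @param table A `composition_table` resolving every food the scenario uses.
#' @param supplements Optional `nutrient_vector` with basis `"per_day"`,
#'   added to the dietary total.
#' @return A `nutrient_vector` with basis `"per_day"`.
#' @export
daily_intake <- function(s, table, supplements = NULL) {
  stopifnot(inherits(s, "diet_scenario"), inherits(table, "composition_table"))
  flat <- resolve_daily_ingredients(s)
  total <- nutrient_vector(basis = "per_day")
  for (i in seq_len(nrow(flat))) {
    f <- ct_get(table, flat$food_id[i])
    total <- nv_add(total, nv_intake(f$composition, flat$grams[i]))
  }
  if (!is.null(supplements)) {
    stopifnot(inherits(supplements, "nutrient_vector"),
              identical(nv_basis(supplements), "per_day"))
    total <- nv_add(total, supplements)
  }
  total
}

#' Replace one food by another throughout a scenario (mass-preserving)
#'
#' Every occurrence of `old` in every dish is replaced by `new` at identical
#' mass, so total food mass per day is conserved exactly. If `old` does not
#' occur, the scenario is returned unchanged with a warning and the attribute
#' `swap_applied = FALSE`.
#'
#' @param s A `diet_scenario`.
#' @param old,new Food ids.
#' @param table Optional `composition_table`; when given, `new` must resolve
#'   in it.
#' @return The modified `diet_scenario` (attribute `swap_applied` records
#'   whether anything changed).
#' @export
substitute_food <- function(s, old, new, table = NULL) {
  stopifnot(inherits(s, "diet_scenario"))
  if (!is.null(table)) ct_get(table, new)  # errors if unresolvable
  hit <- FALSE
  for (did in names(s$dishes)) {
    ing <- s$dishes[[did]]$ingredients
    m <- ing$food_id == old
    if (any(m)) {
      hit <- TRUE
      ing$food_id[m] <- new
      # merge rows if new already present in the dish
      agg <- stats::aggregate(grams ~ food_id, data = ing, FUN = sum)
      s$dishes[[did]]$ingredients <- agg[, c("food_id", "grams")]
    }
  }
  if (!hit) warning("substitute_food: '", old, "' not present; no-op",
                    call. = FALSE)
  attr(s, "swap_applied") <- hit
  s
}

#' Append a food addition to a scenario
#'
#' Adds `grams` of `food_id` as an extra meal (used for micronutrient-rich
#' food additions such as one mango or a fried-fish portion).
#'
#' @param s A `diet_scenario`.
#' @param food_id Food to add.
#' @param grams Mass added per day (> 0).
#' @param label Meal label for the addition.
#' @return The modified `diet_scenario`.
#' @export
add_food <- function(s, food_id, grams, label = paste0("add_", food_id)) {
  stopifnot(inherits(s, "diet_scenario"), grams > 0)
  did <- paste0("dish_", label)
  d <- dish(did, data.frame(food_id = food_id, grams = grams,
                            stringsAsFactors = FALSE))
  if (did %in% names(s$dishes)) stop("addition dish already exists: ", did,
                                     call. = FALSE)
  s$dishes[[did]] <- d
  s$plan$meals <- c(s$plan$meals,
                    list(list(label = label,
                              dishes = data.frame(dish_id = did,
                                                  multiplier = 1,
                                                  stringsAsFactors = FALSE))))
  s
}

# --- scenario (de)serialization ----------------------------------------------

#' Write a diet scenario to a JSON file
#' @param s A `diet_scenario`.
#' @param path Output path, or `NULL` to return the JSON string.
#' @return The JSON string, invisibly.
#' @export
write_scenario <- function(s, path = NULL) {
  stopifnot(inherits(s, "diet_scenario"))
  obj <- list(
    scenario = list(country = s$country, setting = s$setting,
                    group = s$group$id, body_weight = s$group$body_weight),
    dishes = lapply(unname(s$dishes), function(d)
      list(dish_id = d$dish_id, ingredients = d$ingredients)),
    meals = lapply(s$plan$meals, function(m)
      list(label = m$label, dishes = m$dishes))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(as.character(js))
}

#' Read a diet scenario from a JSON file
#' @param source Path to a JSON file, or a JSON string.
#' @return A `diet_scenario`.
#' @export
read_scenario <- function(source) {
  obj <- jsonlite::fromJSON(source, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
  dishes <- lapply(seq_len(length(obj$dishes$dish_id)), function(i)
    dish(obj$dishes$dish_id[i],
         as.data.frame(obj$dishes$ingredients[[i]])))
  meals <- lapply(seq_len(length(obj$meals$label)), function(i)
    list(label = obj$meals$label[i],
         dishes = as.data.frame(obj$meals$dishes[[i]])))
  diet_scenario(country = obj$scenario$country, setting = obj$scenario$setting,
                group = population_group(obj$scenario$group,
                                         obj$scenario$body_weight),
                plan = meal_plan(meals), dishes = dishes)
}
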