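# The four intervention layer types (fortification, biofortification,
# supplementation, food swaps) and their composition with a base diet.

# Fortificant registry: which tracked nutrient each compound carries, its
# elemental mass fraction, and how a level converts to added nutrient per g
# of vehicle. Compounds carrying untracked B vitamins are accepted and
# contribute nothing to the six tracked nutrients.
FORTIFICANTS <- list(
  potassium_iodate = list(nutrient = "iodine",    fraction = NA), # via iodate
  sodium_iodate    = list(nutrient = "iodine",    fraction = NA),
  calcium_iodate   = list(nutrient = "iodine",    fraction = NA),
  retinyl_palmitate = list(nutrient = "vitamin_a", fraction = NA), # via RAE
  ferrous_fumarate = list(nutrient = "iron",      fraction = 0.328),
  zinc_oxide       = list(nutrient = "zinc",      fraction = 0.803),
  folic_acid       = list(nutrient = "folate",    fraction = 1.0),
  niacinamide      = list(nutrient = "niacin",    fraction = 1.0),
  niacin           = list(nutrient = "niacin",    fraction = 1.0),
  thiamine         = list(nutrient = NA,          fraction = 1.0),
  riboflavin       = list(nutrient = NA,          fraction = 1.0),
  pyridoxine       = list(nutrient = NA,          fraction = 1.0),
  cyanocobalamin   = list(nutrient = NA,          fraction = 1.0)
)

IODATE_COMPOUND <- c(potassium_iodate = "KIO3", sodium_iodate = "NaIO3",
                     calcium_iodate = "Ca_IO3_2")

#' Define a fortification layer
#'
#' Mass fortification of a vehicle food (salt, vegetable oil, wheat flour).
#' Each addition is a fortificant compound with a level: mass of compound per
#' kg of vehicle (`"mg/kg"`; `"g/t"` and `"ppm"` are the same quantity) or
#' vitamin A activity per gram (`"IU/g"`). When `elemental_equivalent` is
#' `TRUE`, mass levels are read as elemental nutrient mass rather than
#' compound mass (regulations state levels both ways; the flag makes both
#' readings expressible).
#'
#' @param vehicle Vehicle `food_id`.
#' @param additions A list of `list(compound =, level =, unit =)` entries;
#'   levels must be >= 0. Units: `"mg/kg"`, `"g/t"`, `"ppm"`, `"IU/g"`.
#' @param elemental_equivalent Read mass levels as elemental nutrient mass.
#' @param mandatory Mandatory (national standard) or voluntary program.
#' @param name Layer label used in contribution maps.
#' @return An object of class `fortification_spec`.
#' @export
fortification_spec <- function(vehicle, additions,
                               elemental_equivalent = FALSE,
                               mandatory = TRUE,
                               name = paste0("fortify_", vehicle)) {
  stopifnot(is.character(vehicle), length(vehicle) == 1, is.list(additions))
  for (a in additions) {
    stopifnot(!is.null(a$compound), !is.null(a$level), !is.null(a$unit))
    if (!a$compound %in% names(FORTIFICANTS)) {
      stop("unknown fortificant: ", a$compound, call. = FALSE)
    }
    if (!a$unit %in% c("mg/kg", "g/t", "ppm", "IU/g")) {
      stop("unknown level unit: ", a$unit, call. = FALSE)
    }
    if (!is.finite(a$level) || a$level < 0) {
      stop("fortification level must be >= 0", call. = FALSE)
    }
  }
  structure(list(vehicle = vehicle, additions = additions,
                 elemental_equivalent = elemental_equivalent,
                 mandatory = mandatory, name = name),
            class = c("fortification_spec", "intervention_layer"))
}

# Added nutrient density per gram of vehicle, in canonical units
# (mg/g for iron/zinc/niacin, ug/g for vitamin A/folate/iodine).
fortificant_density_per_g <- function(a, elemental_equivalent = FALSE) {
  info <- FORTIFICANTS[[a$compound]]
  if (is.na(info$nutrient)) return(NULL)
  if (a$unit == "IU/g") {
    if (!identical(info$nutrient, "vitamin_a")) {
      stop("IU/g level only valid for vitamin A compounds", call. = FALSE)
    }
    return(list(nutrient = "vitamin_a",
                per_g = to_ug_rae("retinol_iu", a$level)))
  }
  # mg/kg == g/t == ppm: level mg compound per kg vehicle
  level <- a$level
  per_g <- switch(info$nutrient,
    iodine = {
      el <- if (elemental_equivalent) level else
        iodate_to_iodine(IODATE_COMPOUND[[a$compound]], level)
      el                                    # mg/kg == ug/g
    },
    vitamin_a = to_ug_rae("retinyl_palmitate_mass", level) / 1000, # ug RAE/g
    folate = {
      el <- level * if (elemental_equivalent) 1 else info$fraction
      el                                    # mg/kg == ug/g
    },
    {
      el <- level * if (elemental_equivalent) 1 else info$fraction
      el / 1000                             # mg per g for iron/zinc/niacin
    })
  list(nutrient = info$nutrient, per_g = per_g)
}

# Per-100 g nutrient_vector added to the vehicle by a fortification spec.
fortification_added_per_100g <- function(f) {
  add <- stats::setNames(numeric(length(NUTRIENTS)), NUTRIENTS)
  for (a in f$additions) {
    d <- fortificant_density_per_g(a, f$elemental_equivalent)
    if (!is.null(d)) add[d$nutrient] <- add[d$nutrient] + 100 * d$per_g
  }
  as_nutrient_vector(add, "per_100g")
}

#' Apply a fortification layer to a composition table
#'
#' Returns a copy of the table in which the vehicle's composition is that of
#' the fortified product: basal composition plus the elemental/RAE-converted
#' nutrient mass corresponding to each addition level. Replacement semantics
#' make the operation idempotent: applying the same spec to an
#' already-fortified table (tagged per spec name) does not double the
#' addition.
#'
#' @param table A `composition_table`.
#' @param f A `fortification_spec` whose vehicle exists in `table`.
#' @return A new `composition_table`; the input is unmodified.
#' @export
apply_fortification <- function(table, f) {
  stopifnot(inherits(table, "composition_table"),
            inherits(f, "fortification_spec"))
  veh <- ct_get(table, f$vehicle)
  tag <- paste0("fortified:", f$name)
  if (tag %in% veh$tags) return(table)   # already applied: idempotent
  veh$composition <- nv_add(veh$composition, fortification_added_per_100g(f))
  veh$tags <- unique(c(veh$tags, tag))
  ct_set(table, veh)
}

#' Define a biofortification layer
#'
#' Biofortification replaces the basal composition of the target food
#' wholesale with the composition of the biofortified product (e.g. maize
#' porridge made from provitamin A maize).
#'
#' @param target Target `food_id`.
#' @param replacement A `nutrient_vector` (per 100 g) for the biofortified
#'   product.
#' @param name Layer label.
#' @return An object of class `biofortification_spec`.
#' @export
biofortification_spec <- function(target, replacement,
                                  name = paste0("biofortify_", target)) {
  stopifnot(is.character(target), length(target) == 1,
            inherits(replacement, "nutrient_vector"),
            identical(attr(replacement, "basis"), "per_100g"))
  structure(list(target = target, replacement = replacement, name = name),
            class = c("biofortification_spec", "intervention_layer"))
}

#' Apply a biofortification layer to a composition table
#'
#' @param table A `composition_table`.
#' @param b A `biofortification_spec` whose target exists in `table`.
#' @return A new table with the target's composition replaced (idempotent).
#' @export
apply_biofortification <- function(table, b) {
  stopifnot(inherits(table, "composition_table"),
            inherits(b, "biofortification_spec"))
  tgt <- ct_get(table, b$target)
  tgt$composition <- b$replacement
  ct_set(table, tgt)
}

#' Define a supplementation layer
#'
#' @param name Layer label (e.g. `"ifa"`, `"vas"`).
#' @param doses A `nutrient_vector` (per day) of supplemental nutrients.
#' @param schedule `"daily"` for routine supplements (iron-folic-acid), or
#'   `"single_high_dose"` for one-off doses (post-partum vitamin A); a
#'   single high dose is counted in full on the simulated day.
#' @return An object of class `supplement_spec`.
#' @export
supplement_spec <- function(name, doses,
                            schedule = c("daily", "single_high_dose")) {
  schedule <- match.arg(schedule)
  stopifnot(inherits(doses, "nutrient_vector"),
            identical(attr(doses, "basis"), "per_day"))
  structure(list(name = name, doses = doses, schedule = schedule),
            class = c("supplement_spec", "intervention_layer"))
}

#' Add a supplement to a daily intake vector
#'
#' @param intake A `nutrient_vector` (per day).
#' @param s A `supplement_spec`.
#' @return Element-wise sum, per day.
#' @export
apply_supplement <- function(intake, s) {
  stopifnot(inherits(s, "supplement_spec"))
  nv_add(intake, s$doses)
}

#' Define a food-swap layer
#'
#' Either adds a fixed mass of a micronutrient-rich food to the day
#' (`action = "add"`, e.g. one 100 g mango) or replaces every occurrence of
#' one food by another at identical mass (`action = "replace"`, e.g. basic
#' vegetable oil by red palm oil).
#'
#' @param action `"add"` or `"replace"`.
#' @param food_id,grams For `"add"`: food added and its mass (> 0).
#' @param old_id,new_id For `"replace"`: the food replaced and its stand-in.
#' @param name Layer label.
#' @return An object of class `food_swap_spec`.
#' @export
food_swap_spec <- function(action = c("add", "replace"), food_id = NULL,
                           grams = NULL, old_id = NULL, new_id = NULL,
                           name = NULL) {
  action <- match.arg(action)
  if (action == "add") {
    stopifnot(is.character(food_id), length(grams) == 1, grams > 0)
    if (is.null(name)) name <- paste0("add_", food_id)
  } else {
    stopifnot(is.character(old_id), is.character(new_id))
    if (is.null(name)) name <- paste0("swap_", old_id, "_", new_id)
  }
  structure(list(action = action, food_id = food_id, grams = grams,
                 old_id = old_id, new_id = new_id, name = name),
            class = c("food_swap_spec", "intervention_layer"))
}

apply_food_swap <- function(scenario, sw, table = NULL) {
  if (sw$action == "add") {
    add_food(scenario, sw$food_id, sw$grams, label = sw$name)
  } else {
    suppressWarnings(substitute_food(scenario, sw$old_id, sw$new_id, table))
  }
}

layer_name <- function(l) l$name

layer_type_order <- function(l) {
  if (inherits(l, "biofortification_spec")) 1L
  else if (inherits(l, "fortification_spec")) 2L
  else if (inherits(l, "food_swap_spec")) 3L
  else if (inherits(l, "supplement_spec")) 4L
  else stop("unknown intervention layer type", call. = FALSE)
}

#' Bundle a base diet scenario with intervention layers
#'
#' @param base A `diet_scenario`.
#' @param layers A list of intervention layers (fortification,
#'   biofortification, supplement, food-swap specs). At most one fortification
#'   layer per vehicle is allowed.
#' @param label Bundle label used in reports.
#' @return An object of class `scenario_bundle`.
#' @export
scenario_bundle <- function(base, layers = list(), label = "scenario") {
  stopifnot(inherits(base, "diet_scenario"), is.list(layers))
  for (l in layers) {
    if (!inherits(l, "intervention_layer")) {
      stop("all layers must be intervention layer specs", call. = FALSE)
    }
  }
  vehicles <- vapply(layers, function(l)
    if (inherits(l, "fortification_spec")) l$vehicle else NA_character_,
    character(1))
  vehicles <- vehicles[!is.na(vehicles)]
  if (anyDuplicated(vehicles)) {
    stop("conflicting layers: two fortifications on vehicle ",
         vehicles[duplicated(vehicles)][1], call. = FALSE)
  }
  structure(list(base = base, layers = layers, label = label),
            class = "scenario_bundle")
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat("<scenario_bundle '", x$label, "': ", length(x$layers), " layers>\n",
      sep = "")
  invisible(x)
}

#' Resolve a scenario bundle to total daily intake and layer contributions
#'
#' Layers are applied in the fixed order biofortification -> fortification ->
#' food swaps -> supplements (stable within each type). The contribution of
#' layer L is the intake with layers up to and including L minus the intake
#' with layers up to L-1, so contributions always sum (with the base intake)
#' to the total. For layers touching disjoint foods, application order does
#' not affect the total.
#'
#' @param bundle A `scenario_bundle`.
#' @param table The basal `composition_table`.
#' @return A list with elements `total` (per-day `nutrient_vector`), `base`
#'   (basal intake), and `contributions` (named list of per-day
#'   `nutrient_vector`s, one per layer, in application order).
#' @export
compose_bundle <- function(bundle, table) {
  stopifnot(inherits(bundle, "scenario_bundle"),
            inherits(table, "composition_table"))
  ord <- order(vapply(bundle$layers, layer_type_order, integer(1)))
  layers <- bundle$layers[ord]

  scen <- bundle$base
  tab <- table
  supp <- nutrient_vector(basis = "per_day")
  base_intake <- daily_intake(scen, tab, supp)
  prev <- base_intake
  contribs <- list()
  for (l in layers) {
    if (inherits(l, "biofortification_spec")) {
      tab <- apply_biofortification(tab, l)
    } else if (inherits(l, "fortification_spec")) {
      tab <- apply_fortification(tab, l)
    } else if (inherits(l, "food_swap_spec")) {
      scen <- apply_food_swap(scen, l, tab)
    } else if (inherits(l, "supplement_spec")) {
      supp <- apply_supplement(supp, l)
    }
    cur <- daily_intake(scen, tab, supp)
    contribs[[layer_name(l)]] <-
      as_nutrient_vector(as.numeric(cur) - as.numeric(prev), "per_day")
    prev <- cur
  }
  list(total = prev, base = base_intake, contributions = contribs)
}
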