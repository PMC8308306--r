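# Food composition data model, CSV I/O, and nutrient-unit conversions.

#' Tracked micronutrients and their canonical units
#'
#' The simulator tracks six micronutrients. Every amount in the package is
#' carried in the nutrient's canonical unit: iron and zinc in mg, vitamin A
#' in µg retinol equivalents (RE/RAE), niacin in mg, folate and iodine in µg.
#'
#' @return A data.frame with columns `nutrient` and `unit`.
#' @export
#' @examples
#' nutrient_units()
nutrient_units <- function() {
  data.frame(
    nutrient = c("iron", "zinc", "vitamin_a", "niacin", "folate", "iodine"),
    unit     = c("mg", "mg", "ug_RE", "mg", "ug", "ug"),
    stringsAsFactors = FALSE
  )
}

NUTRIENTS <- c("iron", "zinc", "vitamin_a", "niacin", "folate", "iodine")

#' Create a nutrient vector
#'
#' A nutrient vector holds one amount per tracked micronutrient, in the
#' nutrient's canonical unit, on a stated basis: `"per_100g"` (composition of
#' a food, per 100 g edible portion) or `"per_day"` (daily intake). Amounts
#' for unnamed nutrients default to 0; unknown nutrient names are rejected.
#' Vectors with different bases cannot be added.
#'
#' @param ... Named amounts, e.g. `iron = 5, folate = 120`. All must be
#'   non-negative and finite.
#' @param basis `"per_100g"` or `"per_day"`.
#' @return A named numeric vector of class `nutrient_vector`.
#' @export
#' @examples
#' nutrient_vector(iron = 5, folate = 120, basis = "per_day")
nutrient_vector <- function(..., basis = c("per_100g", "per_day")) {
  basis <- match.arg(basis)
  amounts <- c(...)
  vals <- stats::setNames(numeric(length(NUTRIENTS)), NUTRIENTS)
  if (length(amounts)) {
    if (is.null(names(amounts)) || any(names(amounts) == "")) {
      stop("all nutrient amounts must be named", call. = FALSE)
    }
    unknown <- setdiff(names(amounts), NUTRIENTS)
    if (length(unknown)) {
      stop("unknown nutrient id(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (any(!is.finite(amounts)) || any(amounts < 0)) {
      stop("nutrient amounts must be finite and non-negative", call. = FALSE)
    }
    vals[names(amounts)] <- amounts
  }
  structure(vals, basis = basis, class = "nutrient_vector")
}

#' Coerce a plain numeric vector to a nutrient vector
#'
#' @param x Numeric vector of length 6, in canonical nutrient order
#'   (or named by nutrient id).
#' @param basis `"per_100g"` or `"per_day"`.
#' @return A `nutrient_vector`.
#' @export
as_nutrient_vector <- function(x, basis) {
  stopifnot(is.numeric(x), length(x) == length(NUTRIENTS))
  if (is.null(names(x))) names(x) <- NUTRIENTS
  x <- x[NUTRIENTS]
  structure(x, basis = basis, class = "nutrient_vector")
}

#' @export
print.nutrient_vector <- function(x, ...) {
  cat("<nutrient_vector basis=", attr(x, "basis"), ">\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

nv_basis <- function(x) attr(x, "basis")

#' Add two nutrient vectors
#'
#' Element-wise addition; both operands must share the same basis.
#' @param a,b Nutrient vectors.
#' @return A nutrient vector on the common basis.
#' @export
nv_add <- function(a, b) {
  stopifnot(inherits(a, "nutrient_vector"), inherits(b, "nutrient_vector"))
  if (!identical(nv_basis(a), nv_basis(b))) {
    stop("cannot add nutrient vectors with different bases (",
         nv_basis(a), " vs ", nv_basis(b), ")", call. = FALSE)
  }
  as_nutrient_vector(as.numeric(a) + as.numeric(b), nv_basis(a))
}

#' Scale a nutrient vector by a non-negative scalar
#' @param a A nutrient vector.
#' @param k A single non-negative number.
#' @return A nutrient vector on the same basis.
#' @export
nv_scale <- function(a, k) {
  stopifnot(inherits(a, "nutrient_vector"), length(k) == 1, is.finite(k),
            k >= 0)
  as_nutrient_vector(as.numeric(a) * k, nv_basis(a))
}

#' Daily intake contributed by a mass of one food
#'
#' Converts a per-100 g composition into a per-day intake for `grams` of the
#' food consumed.
#' @param composition A `nutrient_vector` with basis `"per_100g"`.
#' @param grams Mass consumed per day (g), non-negative.
#' @return A `nutrient_vector` with basis `"per_day"`.
#' @export
nv_intake <- function(composition, grams) {
  stopifnot(inherits(composition, "nutrient_vector"),
            identical(nv_basis(composition), "per_100g"),
            length(grams) == 1, is.finite(grams), grams >= 0)
  as_nutrient_vector(as.numeric(composition) * grams / 100, "per_day")
}

#' Create a food item
#'
#' @param food_id Unique identifier within a composition table.
#' @param name Human-readable name.
#' @param state `"raw"` or `"cooked"`; compositions are as-consumed, so
#'   cooked entries are preferred where cooking changes nutrient content.
#' @param composition A `nutrient_vector` on the per-100 g basis.
#' @param tags Character vector of tags (e.g. `"fortification-vehicle"`,
#'   `"staple"`, `"snack"`).
#' @return An object of class `food_item`.
#' @export
food_item <- function(food_id, name = food_id, state = c("cooked", "raw"),
                      composition = nutrient_vector(basis = "per_100g"),
                      tags = character()) {
  state <- match.arg(state)
  stopifnot(is.character(food_id), length(food_id) == 1, nzchar(food_id),
            inherits(composition, "nutrient_vector"),
            identical(nv_basis(composition), "per_100g"))
  structure(list(food_id = food_id, name = name, state = state,
                 composition = composition, tags = as.character(tags)),
            class = "food_item")
}

#' Create a composition table
#'
#' An immutable lookup of `food_item`s by `food_id`. Interventions never
#' modify a table in place; they return modified copies.
#'
#' @param foods A list of `food_item` objects.
#' @param provenance Free-text provenance note.
#' @return An object of class `composition_table`.
#' @export
composition_table <- function(foods = list(), provenance = "") {
  stopifnot(is.list(foods))
  ids <- vapply(foods, function(f) {
    if (!inherits(f, "food_item")) stop("all entries must be food_item objects",
                                        call. = FALSE)
    f$food_id
  }, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate food_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(foods) <- ids
  structure(list(foods = foods, provenance = provenance),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat("<composition_table: ", length(x$foods), " foods>\n", sep = "")
  invisible(x)
}

#' Look up a food by id
#' @param table A `composition_table`.
#' @param food_id Food identifier; unknown ids fail explicitly.
#' @return The `food_item`.
#' @export
ct_get <- function(table, food_id) {
  stopifnot(inherits(table, "composition_table"))
  f <- table$foods[[food_id]]
  if (is.null(f)) stop("unknown food_id: ", food_id, call. = FALSE)
  f
}

#' Return a copy of the table with one food replaced or inserted
#' @param table A `composition_table`.
#' @param food A `food_item`.
#' @return A new `composition_table`; the input is not modified.
#' @export
ct_set <- function(table, food) {
  stopifnot(inherits(table, "composition_table"), inherits(food, "food_item"))
  table$foods[[food$food_id]] <- food
  table
}

#' Food ids present in a composition table
#' @param table A `composition_table`.
#' @return Character vector of food ids.
#' @export
ct_ids <- function(table) names(table$foods)

# canonical CSV dialect: column name -> meaning
default_dialect <- function() {
  c(food_id = "food_id", name = "name", state = "state",
    iron = "iron_mg", zinc = "zinc_mg", vitamin_a = "vitamin_a_ug_re",
    niacin = "niacin_mg", folate = "folate_ug", iodine = "iodine_ug",
    tags = "tags")
}

# Parse decimals that may use a comma separator ("3,9" -> 3.9).
parse_amount <- function(x) {
  x <- trimws(as.character(x))
  x[x == "" | is.na(x)] <- "0"
  suppressWarnings(as.numeric(gsub(",", ".", x, fixed = TRUE)))
}

#' Read a food composition table from CSV
#'
#' The canonical schema has columns `food_id,name,state,iron_mg,zinc_mg,
#' vitamin_a_ug_re,niacin_mg,folate_ug,iodine_ug,tags` on a per-100 g edible
#' portion basis; `tags` is `;`-separated. A `dialect` mapping allows other
#' column names. Decimal commas are accepted and normalized.
#'
#' @param source Path to a CSV file, or a character vector of CSV lines.
#' @param dialect Named character vector mapping canonical fields to column
#'   names in the file; defaults to the canonical schema.
#' @param provenance Provenance note stored on the table.
#' @return A `composition_table`.
#' @export
read_composition_table <- function(source, dialect = default_dialect(),
                                   provenance = "csv") {
  txt <- if (length(source) == 1 && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  df <- tryCatch(
    utils::read.csv(text = txt, stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) stop("malformed CSV: ", conditionMessage(e),
                             call. = FALSE))
  missing_cols <- setdiff(unname(dialect), names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) return(composition_table(provenance = provenance))
  foods <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    amounts <- vapply(NUTRIENTS, function(n) parse_amount(df[i, dialect[[n]]]),
                      numeric(1))
    if (any(is.na(amounts))) {
      stop("row ", i, ": unparseable amount", call. = FALSE)
    }
    if (any(amounts < 0)) {
      stop("row ", i, ": negative amount", call. = FALSE)
    }
    comp <- as_nutrient_vector(amounts, "per_100g")
    tags <- df[i, dialect[["tags"]]]
    tags <- if (is.na(tags) || !nzchar(tags)) character() else
      strsplit(tags, ";", fixed = TRUE)[[1]]
    foods[[i]] <- food_item(
      food_id = df[i, dialect[["food_id"]]],
      name = df[i, dialect[["name"]]],
      state = df[i, dialect[["state"]]],
      composition = comp, tags = tags)
  }
  composition_table(foods, provenance = provenance)
}

#' Write a composition table to CSV (canonical schema)
#'
#' @param table A `composition_table`.
#' @param path Output path, or `NULL` to return the CSV text invisibly.
#' @return The CSV lines, invisibly.
#' @export
write_composition_table <- function(table, path = NULL) {
  stopifnot(inherits(table, "composition_table"))
  rows <- lapply(table$foods, function(f) {
    a <- as.numeric(f$composition)
    data.frame(food_id = f$food_id, name = f$name, state = f$state,
               iron_mg = a[1], zinc_mg = a[2], vitamin_a_ug_re = a[3],
               niacin_mg = a[4], folate_ug = a[5], iodine_ug = a[6],
               tags = paste(f$tags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(food_id = character(), name = character(), state = character(),
               iron_mg = numeric(), zinc_mg = numeric(),
               vitamin_a_ug_re = numeric(), niacin_mg = numeric(),
               folate_ug = numeric(), iodine_ug = numeric(),
               tags = character(), stringsAsFactors = FALSE)
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  close(con)
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

# --- vitamin A unit conversions ---------------------------------------------

# 1 IU retinol = 0.3 ug RAE (the post-partum 200,000 IU dose is then exactly
# 20x the 3000 ug RAE/day upper limit).
IU_RETINOL_TO_UG_RAE <- 0.3
# ug RAE per mg retinyl palmitate (molar: 286.45/524.86 * 1000 ~ 546; the
# conventional factor 550 is used and is configurable at call sites).
RETINYL_PALMITATE_UG_RAE_PER_MG <- 550

#' Convert a vitamin A quantity to µg RAE
#'
#' Supported forms and conversions:
#' * `retinol_iu`: magnitude in IU, × 0.3 µg RAE/IU;
#' * `retinyl_palmitate_mass`: magnitude in mg, × `palmitate_factor`
#'   (default 550 µg RAE/mg);
#' * `beta_carotene_mass`: magnitude in µg, ÷ `conversion_factor`
#'   (the β-carotene:RE ratio, default 12:1, per-food configurable because
#'   published densities for biofortified crops embed crop-specific factors);
#' * `preformed_rae`: magnitude already in µg RAE, passed through.
#'
#' The conversion is linear in `magnitude` for every form.
#'
#' @param form One of the four forms above.
#' @param magnitude Non-negative quantity in the form's unit.
#' @param conversion_factor β-carotene:RE ratio (> 0), used only for
#'   `beta_carotene_mass`.
#' @param palmitate_factor µg RAE per mg retinyl palmitate (> 0).
#' @return Amount in µg RAE.
#' @export
#' @examples
#' to_ug_rae("retinol_iu", 200000)       # 60000 (20 x the 3000 ug RAE UL)
#' to_ug_rae("beta_carotene_mass", 6)    # 0.5 at the default 12:1 factor
to_ug_rae <- function(form, magnitude, conversion_factor = 12,
                      palmitate_factor = RETINYL_PALMITATE_UG_RAE_PER_MG) {
  stopifnot(length(form) == 1, is.numeric(magnitude), all(magnitude >= 0))
  switch(form,
    retinol_iu = magnitude * IU_RETINOL_TO_UG_RAE,
    retinyl_palmitate_mass = {
      stopifnot(palmitate_factor > 0)
      magnitude * palmitate_factor
    },
    beta_carotene_mass = {
      stopifnot(conversion_factor > 0)
      magnitude / conversion_factor
    },
    preformed_rae = magnitude,
    stop("unknown vitamin A form: ", form, call. = FALSE)
  )
}

# iodine mass fractions of iodate salts, from atomic masses
# (K 39.0983, Na 22.98977, Ca 40.078, I 126.90447, O 15.999)
iodate_fractions <- function() {
  I <- 126.90447; O <- 15.999
  c(KIO3      = I / (39.0983 + I + 3 * O),
    NaIO3     = I / (22.98977 + I + 3 * O),
    Ca_IO3_2  = 2 * I / (40.078 + 2 * (I + 3 * O)))
}

#' Elemental iodine delivered by an iodate compound
#'
#' Salt iodation levels are specified as mass of iodate salt; the iodine
#' actually delivered is the compound mass times its iodine mass fraction
#' (KIO3 0.593, NaIO3 0.641, Ca(IO3)2 0.651, from atomic masses).
#'
#' @param compound `"KIO3"`, `"NaIO3"` or `"Ca_IO3_2"`.
#' @param mass_mg Compound mass in mg (non-negative; any mass unit works,
#'   the result is in the same unit).
#' @return Elemental iodine mass, same unit as `mass_mg`.
#' @export
#' @examples
#' iodate_to_iodine("KIO3", 35) # ~20.76 mg iodine per 35 mg potassium iodate
iodate_to_iodine <- function(compound, mass_mg) {
  stopifnot(is.numeric(mass_mg), all(mass_mg >= 0))
  fr <- iodate_fractions()
  if (!compound %in% names(fr)) {
    stop("unknown iodate compound: ", compound, call. = FALSE)
  }
  unname(fr[[compound]]) * mass_mg
}
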