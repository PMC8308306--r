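# Reference-value registry and coverage/risk computation
# (%EAR, %RNI, %UL, risk classification).

#' Round half away from zero
#'
#' Printed intake tables use commercial rounding (0.5 rounds up), not the
#' banker's rounding of base `round()`.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build a reference-value set
#'
#' One row per nutrient x population group with the estimated average
#' requirement (EAR), recommended nutrient intake (RNI) and upper limit (UL)
#' per day in the nutrient's canonical unit. UL may be `NA` (no UL assessed,
#' e.g. zinc for pregnant/lactating women in the packaged fixture). Iron and
#' zinc references are bioavailability-specific; the `bioavailability` column
#' records the assumption and `source` records provenance (WHO/FAO, IoM, or
#' back-calculated).
#'
#' @param df Data frame with columns `nutrient`, `group`, `ear`, `rni`, `ul`,
#'   `bioavailability`, `source`.
#' @param iodine_rate µg iodine per kg body weight per day used for the
#'   iodine UL rule, named by group (default 30 for NPNL, 40 for PL women).
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(df, iodine_rate = c(npnl = 30, pl = 40)) {
  need <- c("nutrient", "group", "ear", "rni", "ul")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  if (!"bioavailability" %in% names(df)) df$bioavailability <- NA_character_
  if (!"source" %in% names(df)) df$source <- NA_character_
  bad <- !is.finite(df$ear) | df$ear <= 0 | !is.finite(df$rni) | df$rni <= 0 |
    (!is.na(df$ul) & df$ul <= 0)
  if (any(bad)) stop("EAR and RNI must be > 0; UL, when present, > 0",
                     call. = FALSE)
  if (anyDuplicated(df[, c("nutrient", "group")])) {
    stop("duplicate (nutrient, group) reference rows", call. = FALSE)
  }
  structure(list(values = df, iodine_rate = iodine_rate),
            class = "reference_set")
}

#' Look up one reference row
#' @param refs A `reference_set`.
#' @param nutrient Nutrient id.
#' @param group Group id (`"npnl"` or `"pl"`).
#' @return One-row data frame.
#' @export
ref_get <- function(refs, nutrient, group) {
  stopifnot(inherits(refs, "reference_set"))
  r <- refs$values[refs$values$nutrient == nutrient &
                   refs$values$group == group, , drop = FALSE]
  if (nrow(r) != 1) {
    stop("missing reference for (", nutrient, ", ", group, ")", call. = FALSE)
  }
  r
}

#' Iodine upper limit from body weight
#'
#' The iodine UL is body-weight-proportional: rate (µg/kg/day) times assumed
#' body weight (30 µg/kg/day at 55 kg for NPNL women, 40 µg/kg/day at 65 kg
#' for pregnant or lactating women).
#'
#' @param rate µg iodine per kg body weight per day (> 0).
#' @param body_weight kg (> 0).
#' @return UL in µg/day.
#' @export
#' @examples
#' iodine_ul(30, 55) # 1650
#' iodine_ul(40, 65) # 2600
iodine_ul <- function(rate, body_weight) {
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0)
    stop("rate must be a single positive number", call. = FALSE)
  if (!is.numeric(body_weight) || length(body_weight) != 1 ||
      !is.finite(body_weight) || body_weight <= 0)
    stop("body_weight must be a single positive number", call. = FALSE)
  rate * body_weight
}

# Risk classification from unrounded intake and thresholds. Above-UL is
# checked first (an intake can exceed the UL while failing the EAR when the
# back-calculated EAR sits above the RNI, as for iron in PL women).
classify_intake <- function(intake, ear, rni, ul) {
  if (!is.na(ul) && intake > ul) "above_UL"
  else if (intake < ear) "below_EAR"
  else if (intake < rni) "EAR_to_RNI"
  else "adequate"
}

#' Coverage of reference values by a daily intake
#'
#' For each tracked nutrient computes the percentage of the EAR, RNI and UL
#' covered by the intake (integers, rounded half away from zero, matching
#' printed-table precision) and a risk class. Classification always uses
#' unrounded ratios: `above_UL` if and only if the unrounded intake exceeds
#' the UL; otherwise `below_EAR` (< EAR), `EAR_to_RNI` (EAR <= intake < RNI)
#' or `adequate` (>= RNI). When no UL is defined `pct_ul` is `NA` and the
#' `ul_status` column reads `"no_UL_assessment"`.
#'
#' @param intake A per-day `nutrient_vector`.
#' @param refs A `reference_set` complete for `group`.
#' @param group A `population_group` or group id string.
#' @return A data.frame of class `coverage_result` with columns `nutrient`,
#'   `intake`, `pct_ear`, `pct_rni`, `pct_ul`, `class`, `ul_status`, plus
#'   unrounded ratios in the attribute `"raw"`.
#' @export
coverage <- function(intake, refs, group) {
  stopifnot(inherits(intake, "nutrient_vector"),
            identical(attr(intake, "basis"), "per_day"),
            inherits(refs, "reference_set"))
  gid <- if (inherits(group, "population_group")) group$id else group
  out <- vector("list", length(NUTRIENTS))
  raw <- matrix(NA_real_, length(NUTRIENTS), 3,
                dimnames = list(NUTRIENTS, c("ear", "rni", "ul")))
  for (i in seq_along(NUTRIENTS)) {
    n <- NUTRIENTS[i]
    r <- ref_get(refs, n, gid)
    amt <- as.numeric(intake[[n]])
    raw[i, "ear"] <- 100 * amt / r$ear
    raw[i, "rni"] <- 100 * amt / r$rni
    raw[i, "ul"]  <- if (is.na(r$ul)) NA_real_ else 100 * amt / r$ul
    out[[i]] <- data.frame(
      nutrient = n, intake = amt,
      pct_ear = round_half_away(raw[i, "ear"]),
      pct_rni = round_half_away(raw[i, "rni"]),
      pct_ul = if (is.na(r$ul)) NA_real_ else round_half_away(raw[i, "ul"]),
      class = classify_intake(amt, r$ear, r$rni, r$ul),
      ul_status = if (is.na(r$ul)) "no_UL_assessment" else
        if (amt > r$ul) "above_UL" else "ok",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "raw") <- raw
  attr(res, "group") <- gid
  class(res) <- c("coverage_result", class(res))
  res
}

#' Risk summary per nutrient from a coverage result
#'
#' @param c A `coverage_result` from [coverage()].
#' @return Data frame with columns `nutrient`, `class` and `ul_status`.
#' @export
classify <- function(c) {
  stopifnot(inherits(c, "coverage_result"))
  c[, c("nutrient", "class", "ul_status")]
}

#' Read/write reference-value CSV files
#'
#' Columns: `nutrient,group,ear,rni,ul,bioavailability,source`; empty `ul`
#' means no UL assessed.
#'
#' @param source Path to a CSV file or character vector of CSV lines.
#' @return A `reference_set`.
#' @export
read_reference_set <- function(source) {
  txt <- if (length(source) == 1 && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else as.character(source)
  df <- utils::read.csv(text = txt, stringsAsFactors = FALSE)
  reference_set(df)
}

#' @rdname read_reference_set
#' @param refs A `reference_set`.
#' @param path Output path, or `NULL` to return the CSV lines.
#' @export
write_reference_set <- function(refs, path = NULL) {
  stopifnot(inherits(refs, "reference_set"))
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(refs$values, con, row.names = FALSE, quote = TRUE)
  close(con)
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
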