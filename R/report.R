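# Coverage-report rendering (CSV/JSON/markdown) and the command-line
# interface.

#' Build report rows for one resolved scenario
#'
#' Combines a bundle label with the coverage result of its resolved intake.
#' Intakes are reported at 1 decimal place and percentages as integers
#' (matching published-table precision); unrounded values are preserved under
#' the `raw` columns so renderers never re-round.
#'
#' @param label Scenario label.
#' @param cov A `coverage_result` from [coverage()].
#' @return A data.frame (one row per nutrient) of class `report_rows`.
#' @export
report_rows <- function(label, cov) {
  stopifnot(inherits(cov, "coverage_result"))
  df <- data.frame(
    scenario = label,
    nutrient = cov$nutrient,
    intake = round_half_away(cov$intake, 1),
    pct_ear = cov$pct_ear,
    pct_rni = cov$pct_rni,
    pct_ul = cov$pct_ul,
    class = cov$class,
    raw_intake = cov$intake,
    stringsAsFactors = FALSE)
  class(df) <- c("report_rows", class(df))
  df
}

report_columns <- c("scenario", "nutrient", "intake", "pct_ear", "pct_rni",
                    "pct_ul", "class", "raw_intake")

#' Render a coverage report
#'
#' Deterministic rendering of report rows. `"csv"` emits the canonical
#' columns; `"json"` emits an object with a `rows` array carrying the same
#' values plus unrounded intakes under `raw_intake`; `"markdown"` emits a
#' pipe table with a flag column marking reached recommendations (`RNI` when
#' the RNI is covered, `UL!` when the upper limit is exceeded — the published
#' tables' cell shading).
#'
#' @param rows A `report_rows` data.frame (possibly several scenarios
#'   row-bound together).
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @return A character vector of output lines.
#' @export
render_report <- function(rows, format = c("csv", "json", "markdown")) {
  if (!is.character(format) || length(format) != 1 ||
      !format %in% c("csv", "json", "markdown")) {
    stop("unknown report format: ", paste(format, collapse = ","),
         call. = FALSE)
  }
  stopifnot(is.data.frame(rows), all(report_columns %in% names(rows)))
  rows <- as.data.frame(rows)[, report_columns]
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(rows, con, row.names = FALSE, quote = TRUE, na = "")
    close(con)
    out
  } else if (format == "json") {
    as.character(jsonlite::toJSON(list(rows = rows), dataframe = "rows",
                                  auto_unbox = TRUE, digits = NA,
                                  na = "null", pretty = TRUE))
  } else {
    flag <- ifelse(!is.na(rows$pct_ul) & rows$class == "above_UL", "UL!",
                   ifelse(rows$pct_rni >= 100, "RNI", ""))
    hdr <- "| scenario | nutrient | intake | %EAR | %RNI | %UL | flag |"
    sep <- "|---|---|---|---|---|---|---|"
    body <- sprintf("| %s | %s | %s | %s | %s | %s | %s |",
                    rows$scenario, rows$nutrient,
                    format(rows$intake, trim = TRUE, scientific = FALSE),
                    rows$pct_ear, rows$pct_rni,
                    ifelse(is.na(rows$pct_ul), "-", rows$pct_ul), flag)
    c(hdr, sep, body)
  }
}

#' Parse a JSON report back into report rows
#' @param source JSON string or path.
#' @return A `report_rows` data.frame.
#' @export
parse_report_json <- function(source) {
  obj <- jsonlite::fromJSON(source)
  df <- as.data.frame(obj$rows)
  if (!"pct_ul" %in% names(df)) df$pct_ul <- NA_real_
  df$pct_ul <- as.numeric(df$pct_ul)
  df <- df[, report_columns]
  class(df) <- c("report_rows", class(df))
  df
}

# resolve one fixture bundle into report rows
bundle_report_rows <- function(fx, bundle_name) {
  b <- fx$bundles[[bundle_name]]
  if (is.null(b)) {
    stop("no bundle '", bundle_name, "' in this cell; available: ",
         paste(names(fx$bundles), collapse = ", "), call. = FALSE)
  }
  res <- compose_bundle(b, fx$table)
  cov <- coverage(res$total, fx$refs, fx$scenario$group)
  report_rows(paste(fx$manifest$cell, bundle_name, sep = ":"), cov)
}

cli_usage <- function() {
  c("usage: fortisim <subcommand> [options]",
    "",
    "subcommands:",
    "  simulate --country C --setting S --group G [--scenario B] [--format F] [--out PATH]",
    "           run one intervention bundle for one fixture cell",
    "  matrix   --country C [--format F] [--out PATH]",
    "           run every cell x bundle combination for a country",
    "  report   --config PATH [--format F] [--out PATH]",
    "           re-render a JSON report",
    "  fixtures --out DIR",
    "           emit the packaged Benin/Ghana fixture files",
    "",
    "options: --country {benin,ghana} --setting {urban,rural}",
    "         --group {npnl,pl} --format {csv,json,markdown}",
    "         --scenario BUNDLE_LABEL --config PATH --seed INT --out PATH")
}

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    if (i + 1 > length(args)) stop("missing value for ", a, call. = FALSE)
    opts[[substring(a, 3)]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

emit <- function(lines, out = NULL) {
  if (is.null(out)) cat(lines, sep = "\n") else writeLines(lines, out)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (one bundle for one cell), `matrix` (all cells and
#' bundles for a country), `report` (re-render a JSON report), `fixtures`
#' (emit the packaged fixture files). Validation failures return status 1,
#' usage errors and bad paths status 2; diagnostics go to standard error.
#' Output for a fixed configuration is byte-identical across runs.
#'
#' @param args Character vector of command-line arguments (subcommand first).
#' @return Integer exit status (0 on success), invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    writeLines(cli_usage(), con = stderr())
    return(invisible(2L))
  }
  sub <- args[1]
  if (!sub %in% c("simulate", "matrix", "report", "fixtures")) {
    message("unknown subcommand: ", sub)
    writeLines(cli_usage(), con = stderr())
    return(invisible(2L))
  }
  opts <- tryCatch(parse_cli_args(args[-1]), error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts))
    return(invisible(2L))
  }
  fmt <- if (is.null(opts$format)) "markdown" else opts$format
  status <- tryCatch({
    if (sub == "fixtures") {
      if (is.null(opts$out)) stop("fixtures requires --out DIR", call. = FALSE)
      paths <- write_fixture_files(opts$out)
      message("wrote ", length(paths), " fixture files to ", opts$out)
      0L
    } else if (sub == "simulate") {
      for (k in c("country", "setting", "group")) {
        if (is.null(opts[[k]])) stop("simulate requires --", k, call. = FALSE)
      }
      fx <- build_fixture(opts$country, opts$setting, opts$group)
      bname <- if (is.null(opts$scenario)) "diet" else opts$scenario
      rows <- bundle_report_rows(fx, bname)
      emit(render_report(rows, fmt), opts$out)
      0L
    } else if (sub == "matrix") {
      if (is.null(opts$country)) stop("matrix requires --country",
                                      call. = FALSE)
      cells <- fixture_cells()
      cells <- cells[cells$country == opts$country, , drop = FALSE]
      if (nrow(cells) == 0) stop("unknown country: ", opts$country,
                                 call. = FALSE)
      all_rows <- list()
      for (i in seq_len(nrow(cells))) {
        fx <- build_fixture(cells$country[i], cells$setting[i],
                            cells$group[i])
        for (bn in names(fx$bundles)) {
          all_rows[[length(all_rows) + 1]] <- bundle_report_rows(fx, bn)
        }
      }
      rows <- do.call(rbind, all_rows)
      emit(render_report(rows, fmt), opts$out)
      message("rendered ", length(all_rows), " scenario blocks for ",
              opts$country)
      0L
    } else { # report
      if (is.null(opts$config)) stop("report requires --config PATH",
                                     call. = FALSE)
      if (!file.exists(opts$config)) {
        message("no such config file: ", opts$config)
        return(invisible(2L))
      }
      rows <- parse_report_json(opts$config)
      emit(render_report(rows, fmt), opts$out)
      0L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}
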