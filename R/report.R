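#' Currency conversion for reporting
#'
#' All model computation happens in a single internal currency (EUR for the
#' packaged inputs); USD figures are produced at reporting time with the
#' fixed 2021 exchange rate of 1.1827 USD per EUR.
#'
#' @param x numeric monetary value(s).
#' @param from,to `"EUR"` or `"USD"`.
#' @param rate USD per EUR.
#' @return `x` expressed in the target currency.
#' @export
convert_currency <- function(x, from = "EUR", to = "USD", rate = 1.1827) {
  from <- match.arg(from, c("EUR", "USD"))
  to <- match.arg(to, c("EUR", "USD"))
  if (from == to) return(x)
  if (from == "EUR") x * rate else x / rate
}

#' Per-patient cost-effectiveness summary table
#'
#' Assembles the canonical results table — one block per scenario, one row
#' per strategy — with discounted total cost and QALYs, increments, and the
#' ICER or dominance label. Monetary cells are rounded to whole currency
#' units and QALYs to two decimals, the table's presentation granularity;
#' the ICER is computed from unrounded totals before rounding, so it will
#' not generally equal the ratio of the rounded increments.
#'
#' @param results a named list of `cea_result` or `scenario_result` objects
#'   (names used as scenario labels), e.g.
#'   `list(base = run_cea(params), "1" = run_scenario(params, "1")$cea)`.
#' @param currency `"EUR"` or `"USD"` for the monetary columns.
#' @param rate USD-per-EUR conversion rate.
#' @param model_currency currency the results were computed in.
#' @return a data.frame with columns `scenario`, `strategy`, `cost`, `qaly`,
#'   `delta_cost`, `delta_qaly`, `icer` (character: number or dominance
#'   label), plus a `currency` attribute.
#' @export
report_table <- function(results, currency = "USD", rate = 1.1827,
                         model_currency = "EUR") {
  if (length(results) == 0)
    stop("no results to tabulate; pass e.g. list(base = run_cea(params))",
         call. = FALSE)
  if (is.null(names(results))) names(results) <- seq_along(results)
  cv <- function(x) round(convert_currency(x, model_currency, currency, rate))
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    if (inherits(r, "scenario_result")) r <- r$cea
    stopifnot(inherits(r, "cea_result"))
    icer_chr <- if (is.na(r$icer)) r$dominance else
      format(cv(r$icer), big.mark = ",", scientific = FALSE)
    data.frame(
      scenario = nm,
      strategy = c(r$intervention, r$comparator),
      cost = cv(r$cost[c(r$intervention, r$comparator)]),
      qaly = round(r$qaly[c(r$intervention, r$comparator)], 2),
      delta_cost = c(cv(r$delta_cost), NA),
      delta_qaly = c(round(r$delta_qaly, 2), NA),
      icer = c(icer_chr, NA),
      stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "currency") <- currency
  out
}

# polynomial rolling hash over a character scalar (mod 2^31 - 1)
.text_digest <- function(txt) {
  m <- 2147483647
  h <- 17
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% m
  sprintf("%08x", h)
}

#' Run manifest for reproducibility
#'
#' Captures everything needed to reproduce a run: package version, a digest
#' of the parameter set (computed over its canonical JSON serialization),
#' the scenario, the RNG seed, and every structural flag in effect. Two runs
#' with equal manifests produce equal outputs.
#'
#' @param params the `cea_parameters` used.
#' @param scenario scenario id.
#' @param seed RNG seed used for any stochastic stage (`NA` for
#'   deterministic runs).
#' @return a list of class `run_manifest`.
#' @export
run_manifest <- function(params, scenario = "base", seed = NA) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_parameters(params, tmp)
  structure(list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("dtascea")),
    params_digest = .text_digest(paste(readLines(tmp, warn = FALSE),
                                       collapse = "\n")),
    scenario = as.character(scenario),
    seed = seed,
    options = params$options
  ), class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  cat(sprintf("  %s | dtascea %s\n", x$timestamp, x$package_version))
  cat(sprintf("  params %s | scenario %s | seed %s\n", x$params_digest,
              x$scenario, x$seed))
  cat(sprintf("  options: accrual=%s half_cycle=%s include_non_lvo=%s\n",
              x$options$accrual, x$options$half_cycle,
              x$options$include_non_lvo_outcomes))
  invisible(x)
}
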