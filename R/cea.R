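#' Incremental cost-effectiveness analysis of two strategy results
#'
#' Computes the incremental cost and QALYs of the intervention over the
#' comparator, the ICER (or a dominance label), and the net monetary benefit
#' (NMB) at each willingness-to-pay threshold. The ICER is reported from the
#' unrounded totals; presentation-rounded increments are a display concern
#' (see [report_table()]). When the increments fall in opposite quadrants a
#' dominance label replaces the ratio: `DOMINANT` when the intervention is no
#' more costly and no less effective (not both increments zero), `DOMINATED`
#' in the mirror case, `TIE` when both increments are exactly zero. A
#' strategy is called cost-effective at threshold `lambda` when
#' `NMB = delta_qaly * lambda - delta_cost > 0` (strict; ties resolve to the
#' comparator).
#'
#' @param intervention,comparator `strategy_result` objects computed from
#'   the same parameter set.
#' @param thresholds willingness-to-pay values per QALY, in the model
#'   currency.
#' @return an object of class `cea_result`: `intervention`, `comparator`,
#'   per-strategy totals, `delta_cost`, `delta_qaly`, `icer` (numeric) or
#'   `dominance` label, `nmb` and `cost_effective` (both named by
#'   threshold).
#' @export
compute_cea <- function(intervention, comparator,
                        thresholds = c(50000, 80000)) {
  stopifnot(inherits(intervention, "strategy_result"),
            inherits(comparator, "strategy_result"))
  dc <- intervention$total_cost - comparator$total_cost
  de <- intervention$total_qaly - comparator$total_qaly

  dominance <- NA_character_
  icer <- NA_real_
  if (dc == 0 && de == 0) {
    dominance <- "TIE"
  } else if (dc <= 0 && de >= 0) {
    dominance <- "DOMINANT"
  } else if (dc >= 0 && de <= 0) {
    dominance <- "DOMINATED"
  } else {
    icer <- dc / de
  }

  nmb <- de * thresholds - dc
  names(nmb) <- format(thresholds, scientific = FALSE, trim = TRUE)
  structure(list(
    intervention = intervention$strategy, comparator = comparator$strategy,
    cost = c(stats::setNames(intervention$total_cost, intervention$strategy),
             stats::setNames(comparator$total_cost, comparator$strategy)),
    qaly = c(stats::setNames(intervention$total_qaly, intervention$strategy),
             stats::setNames(comparator$total_qaly, comparator$strategy)),
    delta_cost = dc, delta_qaly = de, icer = icer, dominance = dominance,
    thresholds = thresholds, nmb = nmb, cost_effective = nmb > 0
  ), class = "cea_result")
}

#' Run both strategies and compare them
#'
#' Executes the full pipeline (decision tree + Markov model) for DTAS and
#' ITER on one parameter set and returns the incremental comparison of
#' DTAS (intervention) vs ITER (comparator) at the parameter set's
#' willingness-to-pay thresholds.
#'
#' @param params a `cea_parameters` object.
#' @return a `cea_result` (see [compute_cea()]), with the two
#'   `strategy_result` objects attached as `$results`.
#' @export
run_cea <- function(params) {
  dtas <- run_strategy(params, "DTAS")
  iter <- run_strategy(params, "ITER")
  out <- compute_cea(dtas, iter, thresholds = params$econ$thresholds)
  out$results <- list(DTAS = dtas, ITER = iter)
  out
}

# signed incremental ratio for sensitivity analyses; NA when delta_qaly == 0
.icer_value <- function(cea) {
  if (cea$delta_qaly == 0) return(NA_real_)
  cea$delta_cost / cea$delta_qaly
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result: %s vs %s>\n", x$intervention, x$comparator))
  cat(sprintf("  incremental cost %.2f, incremental QALY %.4f\n",
              x$delta_cost, x$delta_qaly))
  if (is.na(x$icer)) {
    cat(sprintf("  %s\n", x$dominance))
  } else {
    cat(sprintf("  ICER %.0f per QALY\n", x$icer))
  }
  for (i in seq_along(x$thresholds)) {
    cat(sprintf("  at threshold %s/QALY: NMB %.0f -> %scost-effective\n",
                names(x$nmb)[i], x$nmb[i],
                if (x$cost_effective[i]) "" else "not "))
  }
  invisible(x)
}
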