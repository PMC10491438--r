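#' Propagate a 90-day mRS distribution to 1 year
#'
#' Multiplies the 90-day outcome distribution (row vector) by the
#' 90-day-to-1-year transition matrix. Functional status after severe stroke
#' is not settled at 90 days — patients may still improve or deteriorate over
#' the first year — so the model anchors the Markov stage on the 1-year
#' distribution rather than the trial's 90-day endpoint.
#'
#' @param p90 named probability vector over the five health states at 90
#'   days.
#' @param t90 5x5 row-stochastic transition matrix, 90 days to 1 year.
#' @return named probability vector over the five states at 1 year.
#' @export
#' @examples
#' p <- c(MRS01 = 0.5, MRS23 = 0.5, MRS4 = 0, MRS5 = 0, DEAD = 0)
#' ninety_day_to_one_year(p, diag(5))
ninety_day_to_one_year <- function(p90, t90) {
  p90 <- .as_state_vector(p90)
  t90 <- .as_state_matrix(t90)
  if (length(p90) != nrow(t90))
    stop("dimension mismatch between distribution and transition matrix",
         call. = FALSE)
  out <- as.vector(p90 %*% t90)
  names(out) <- health_states()
  out
}

#' Run the one-year decision-tree stage
#'
#' Implements the first model stage for one strategy: patients enter with a
#' suspected LVO; with probability `p_lvo` the LVO is confirmed and the
#' patient follows the strategy's acute pathway (flat-panel CT and
#' angiography under DTAS, CT/CTA work-up under ITER, thrombolysis and
#' thrombectomy as indicated), realising the strategy's 90-day mRS
#' distribution and then the 90-day-to-1-year transition. With probability
#' `1 - p_lvo` the work-up excludes an LVO: those patients contribute only
#' the strategy-specific diagnostic cost, since their downstream care is
#' assumed identical between strategies.
#'
#' Year-1 amounts are undiscounted (year 1 is the present). Care costs and
#' utilities of year 1 accrue on the 1-year (post-transition) state
#' distribution, the model's anchor state.
#'
#' @param params a `cea_parameters` object.
#' @param strategy `"DTAS"` or `"ITER"`.
#' @return an object of class `year_one_result`: a list with `strategy`,
#'   `entry_dist` (1-year state distribution of confirmed-LVO patients),
#'   `cost_year1` and `qaly_year1` (per suspected-LVO patient).
#' @export
run_year_one <- function(params, strategy = c("DTAS", "ITER")) {
  strategy <- match.arg(strategy)
  p_lvo <- params$triage$p_lvo
  entry <- ninety_day_to_one_year(params$outcome90d[[strategy]], params$t90)

  u_full <- c(params$utilities, DEAD = 0)[health_states()]
  c_full <- c(params$costs$annual_care, DEAD = 0)[health_states()]

  cost <- p_lvo * (params$costs$acute_lvo[[strategy]] +
                     sum(entry * c_full)) +
    (1 - p_lvo) * params$costs$diag_non_lvo[[strategy]]
  qaly <- p_lvo * sum(entry * u_full)

  if (isTRUE(params$options$include_non_lvo_outcomes)) {
    prof <- params$non_lvo_profile
    if (is.null(prof))
      stop("include_non_lvo_outcomes is TRUE but non_lvo_profile is missing",
           call. = FALSE)
    cost <- cost + (1 - p_lvo) * prof$annual_cost
    qaly <- qaly + (1 - p_lvo) * prof$utility
  }

  structure(list(strategy = strategy, entry_dist = entry,
                 cost_year1 = unname(cost), qaly_year1 = unname(qaly)),
            class = "year_one_result")
}

#' @export
print.year_one_result <- function(x, ...) {
  cat(sprintf("<year_one_result: %s>\n", x$strategy))
  cat("  1-year state distribution (LVO patients):\n    ")
  cat(paste(sprintf("%s %.4f", names(x$entry_dist), x$entry_dist),
            collapse = "  "), "\n")
  cat(sprintf("  year-1 cost %.2f, year-1 QALY %.4f (per suspected-LVO patient)\n",
              x$cost_year1, x$qaly_year1))
  invisible(x)
}
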