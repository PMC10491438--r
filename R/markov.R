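#' Annual death probability for a disability state at a given age
#'
#' Combines the general-population life table with a state-specific hazard
#' multiplier on the annual survival scale:
#' `q(s, a) = 1 - (1 - q0(a))^hr_s`. This keeps the result a probability for
#' any non-negative multiplier, consistent with a proportional-hazards view
#' of excess post-stroke mortality. If the mortality model carries an
#' absolute table `q_abs` (living states x tabulated ages), that table takes
#' precedence and is read directly. Ages outside the tabulated range are
#' clamped to the nearest tabulated age.
#'
#' @param age age in whole years.
#' @param state a living health state label.
#' @param mortality mortality model (see [cea_parameters()]).
#' @return annual death probability in `[0, 1]`.
#' @export
#' @examples
#' m <- list(age = 70:90, q0 = rep(0.1, 21),
#'           hr = c(MRS01 = 1, MRS23 = 2, MRS4 = 3, MRS5 = 4))
#' state_death_probability(75, "MRS23", m) # 1 - 0.9^2 = 0.19
state_death_probability <- function(age, state, mortality) {
  state <- .match_state(state)
  if (state == "DEAD") stop("state must be a living state", call. = FALSE)
  idx <- .age_index(age, mortality$age)
  if (!is.null(mortality$q_abs)) return(unname(mortality$q_abs[state, idx]))
  hr <- mortality$hr[[state]]
  if (is.null(hr)) stop("no hazard multiplier for state ", state,
                        call. = FALSE)
  if (hr < 0) stop("hazard multiplier must be >= 0", call. = FALSE)
  1 - (1 - mortality$q0[idx])^hr
}

.age_index <- function(age, ages) {
  idx <- match(age, ages)
  if (is.na(idx)) idx <- if (age < min(ages)) which.min(ages)
                         else which.max(ages)
  idx
}

# all four living-state death probabilities at one age
.death_probs <- function(age, mortality) {
  idx <- .age_index(age, mortality$age)
  if (!is.null(mortality$q_abs)) return(mortality$q_abs[living_states(), idx])
  1 - (1 - mortality$q0[idx])^mortality$hr[living_states()]
}

#' Advance the cohort by one annual Markov cycle
#'
#' Within each cycle, mortality acts first: from every living state `s`, mass
#' `dist(s) * q(s, age)` moves to `DEAD`. Survivors are then redistributed
#' over the living states by the corresponding row of the annual transition
#' matrix, renormalized over living destinations (the matrix describes mRS
#' change conditional on survival; mortality comes from the separate
#' life-table construction, and this ordering keeps the two sources
#' orthogonal). `DEAD` mass stays put.
#'
#' @param dist named probability vector over the five states at cycle start.
#' @param age cohort age during the cycle, in years.
#' @param t_annual 5x5 annual transition matrix.
#' @param mortality mortality model.
#' @return named probability vector at cycle end (sums to 1).
#' @export
step_cohort <- function(dist, age, t_annual, mortality) {
  liv <- living_states()
  q <- .death_probs(age, mortality)
  dying <- dist[liv] * q
  surv <- dist[liv] * (1 - q)
  L <- t_annual[liv, liv, drop = FALSE]
  rs <- rowSums(L)
  if (any(rs == 0 & surv > 0))
    stop("annual transition row with no mass on living destinations but ",
         "nonzero survivors: cannot renormalize", call. = FALSE)
  rs[rs == 0] <- 1  # rows with no survivors: normalization is irrelevant
  out <- c(as.vector(surv %*% (L / rs)), dist[["DEAD"]] + sum(dying))
  names(out) <- health_states()
  out
}

#' Run the Markov stage and assemble full-horizon totals
#'
#' Starting from the one-year state distribution, iterates [step_cohort()]
#' for `markov_years` annual cycles (cycle `k` covers calendar year `1 + k`
#' at cohort age `entry_age + k`), accruing per-cycle care costs and
#' utilities on the cycle's occupancy and discounting cycle `k` by
#' `(1 + r)^-k` (year 1 is the present and carries factor 1). Accrual uses
#' end-of-cycle occupancy by default; `options$accrual = "start"` switches to
#' start-of-cycle occupancy, and `options$half_cycle = TRUE` averages the
#' two. Markov-stage amounts are weighted by `p_lvo`, as only
#' confirmed-LVO patients are tracked beyond year 1; totals add the year-one
#' stage unchanged.
#'
#' @param entry a `year_one_result` from [run_year_one()].
#' @param params a `cea_parameters` object.
#' @return an object of class `strategy_result`: `strategy`, `total_cost`,
#'   `total_qaly` (discounted, per suspected-LVO patient), `cost_year1`,
#'   `qaly_year1`, and `trace` (the `(markov_years + 1) x 5` occupancy
#'   matrix; row 0 is the 1-year entry distribution, conditional on LVO).
#' @export
run_markov <- function(entry, params) {
  stopifnot(inherits(entry, "year_one_result"))
  ec <- params$econ
  opt <- params$options
  p_lvo <- params$triage$p_lvo
  u_full <- c(params$utilities, DEAD = 0)[health_states()]
  c_full <- c(params$costs$annual_care, DEAD = 0)[health_states()]

  n_cyc <- as.integer(ec$markov_years)
  trace <- matrix(NA_real_, nrow = n_cyc + 1L, ncol = .n_states,
                  dimnames = list(cycle = 0:n_cyc, state = health_states()))
  trace[1L, ] <- entry$entry_dist

  cost <- entry$cost_year1
  qaly <- entry$qaly_year1
  dist <- entry$entry_dist
  for (k in seq_len(n_cyc)) {
    age <- ec$entry_age + k
    nxt <- step_cohort(dist, age, params$t_annual, params$mortality)
    occ <- switch(opt$accrual, end = nxt, start = dist)
    if (isTRUE(opt$half_cycle)) occ <- (dist + nxt) / 2
    df_c <- (1 + ec$discount_cost)^(-k)
    df_e <- (1 + ec$discount_qaly)^(-k)
    cyc_cost <- p_lvo * sum(occ * c_full)
    cyc_qaly <- p_lvo * sum(occ * u_full)
    if (isTRUE(opt$include_non_lvo_outcomes)) {
      prof <- params$non_lvo_profile
      cyc_cost <- cyc_cost + (1 - p_lvo) * prof$annual_cost
      cyc_qaly <- cyc_qaly + (1 - p_lvo) * prof$utility
    }
    cost <- cost + cyc_cost * df_c
    qaly <- qaly + cyc_qaly * df_e
    dist <- nxt
    trace[k + 1L, ] <- dist
  }

  structure(list(strategy = entry$strategy, total_cost = cost,
                 total_qaly = qaly, cost_year1 = entry$cost_year1,
                 qaly_year1 = entry$qaly_year1, trace = trace),
            class = "strategy_result")
}

#' Run one strategy end to end
#'
#' Convenience wrapper: [run_year_one()] followed by [run_markov()].
#'
#' @inheritParams run_year_one
#' @return a `strategy_result` (see [run_markov()]).
#' @export
run_strategy <- function(params, strategy = c("DTAS", "ITER")) {
  strategy <- match.arg(strategy)
  run_markov(run_year_one(params, strategy), params)
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result: %s>\n", x$strategy))
  cat(sprintf("  discounted totals per patient: cost %.2f, QALY %.4f\n",
              x$total_cost, x$total_qaly))
  cat(sprintf("  (year 1: cost %.2f, QALY %.4f; %d Markov cycles)\n",
              x$cost_year1, x$qaly_year1, nrow(x$trace) - 1L))
  invisible(x)
}
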