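#' One-way (deterministic) sensitivity analysis
#'
#' Re-runs the full pipeline twice with one parameter set to its lower and
#' upper bound (everything else at base case) and records the resulting
#' ICERs. Components of probability vectors are renormalized via
#' [set_param()] so the vector stays on the simplex. When no bounds are
#' given, the conventional default of +/-20% around the base value is used
#' (upper bounds of probabilities are capped at 1).
#'
#' @param params a `cea_parameters` object (base case).
#' @param path dotted parameter path (see [param_value()]).
#' @param low,high bounds for the parameter; default +/-20% of base.
#' @return a one-row data.frame (a tornado entry): `parameter`, `base`,
#'   `low`, `high`, `icer_at_low`, `icer_at_high`, `spread`.
#' @export
one_way <- function(params, path, low = NULL, high = NULL) {
  base <- param_value(params, path)
  if (length(base) != 1)
    stop("one_way varies scalar parameters; '", path, "' is a vector",
         call. = FALSE)
  if (is.null(low)) low <- 0.8 * base
  if (is.null(high)) high <- min(1.2 * base, if (.is_probability_path(params, path)) 1 else Inf)
  if (low > high) stop("low must be <= high", call. = FALSE)
  icer_at <- function(v) .icer_value(run_cea(set_param(params, path, v)))
  il <- icer_at(low)
  ih <- icer_at(high)
  data.frame(parameter = path, base = unname(base), low = low, high = high,
             icer_at_low = il, icer_at_high = ih, spread = abs(il - ih),
             stringsAsFactors = FALSE)
}

.is_probability_path <- function(params, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (parts[1] %in% c("outcome90d", "t90", "t_annual")) return(TRUE)
  identical(path, "triage.p_lvo")
}

#' Tornado analysis over all configured parameter ranges
#'
#' Applies [one_way()] to every entry of `ranges` and orders the results by
#' ICER spread, widest first — the ordering of a tornado diagram.
#'
#' @param params a `cea_parameters` object.
#' @param ranges named list of `c(low, high)` bounds keyed by parameter
#'   path; defaults to `params$owsa_ranges`.
#' @return a data.frame of tornado entries (class `tornado_result`), sorted
#'   by decreasing `spread`.
#' @seealso [plot_tornado()]
#' @export
tornado <- function(params, ranges = params$owsa_ranges) {
  if (length(ranges) == 0) {
    out <- data.frame(parameter = character(), base = numeric(),
                      low = numeric(), high = numeric(),
                      icer_at_low = numeric(), icer_at_high = numeric(),
                      spread = numeric(), stringsAsFactors = FALSE)
  } else {
    rows <- lapply(names(ranges), function(p)
      one_way(params, p, ranges[[p]][1], ranges[[p]][2]))
    out <- do.call(rbind, rows)
    out <- out[order(-out$spread), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("tornado_result", class(out))
  out
}

# ---- probabilistic sensitivity analysis ------------------------------------

# Dirichlet draws via normalized gamma variates
.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  x / rowSums(x)
}

#' Moment-matched PSA distribution descriptors
#'
#' Helpers to build `psa_spec` entries. `psa_beta_spec()` and
#' `psa_gamma_spec()` moment-match a beta (for probabilities and utilities)
#' or gamma (for costs and hazard multipliers) distribution to a mean and
#' standard error; by convention the standard error defaults to 20% of the
#' mean when a source reports only a point estimate. `psa_dirichlet_spec()`
#' builds a Dirichlet descriptor for a multinomial probability vector from
#' its mean and an effective sample size (typically the source trial arm
#' size). `psa_fixed_spec()` pins a parameter at a value.
#'
#' @param mean distribution mean (vector mean for the Dirichlet).
#' @param se standard error; default `0.2 * mean`.
#' @param n effective sample size (Dirichlet concentration = `n * mean`).
#' @param value fixed value.
#' @return a distribution descriptor list for use in `psa_spec`.
#' @export
psa_beta_spec <- function(mean, se = 0.2 * mean) {
  if (mean <= 0 || mean >= 1) stop("beta mean must be in (0,1)", call. = FALSE)
  v <- se^2
  if (v >= mean * (1 - mean))
    stop("beta variance too large for mean ", mean, call. = FALSE)
  nu <- mean * (1 - mean) / v - 1
  list(family = "beta", shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' @rdname psa_beta_spec
#' @export
psa_gamma_spec <- function(mean, se = 0.2 * mean) {
  if (mean <= 0 || se <= 0) stop("gamma mean and se must be > 0",
                                 call. = FALSE)
  shape <- (mean / se)^2
  list(family = "gamma", shape = shape, rate = shape / mean)
}

#' @rdname psa_beta_spec
#' @export
psa_dirichlet_spec <- function(mean, n) {
  if (n <= 0) stop("effective sample size must be > 0", call. = FALSE)
  list(family = "dirichlet", alpha = unname(n * mean / sum(mean)))
}

#' @rdname psa_beta_spec
#' @export
psa_fixed_spec <- function(value) list(family = "fixed", value = value)

.psa_draw <- function(spec, path) {
  switch(spec$family,
    beta = stats::rbeta(1, spec$shape1, spec$shape2),
    gamma = stats::rgamma(1, shape = spec$shape, rate = spec$rate),
    dirichlet = {
      # alpha_i = 0 is the degenerate limit: the category stays at 0
      if (any(spec$alpha < 0) || all(spec$alpha == 0))
        stop("invalid Dirichlet concentration for '", path, "'",
             call. = FALSE)
      as.vector(.rdirichlet(1, spec$alpha))
    },
    fixed = spec$value,
    stop("no distribution declared for sampled parameter '", path, "'",
         call. = FALSE)
  )
}

#' Probabilistic sensitivity analysis (Monte Carlo)
#'
#' Draws `n` parameter sets from the distributions declared in
#' `params$psa_spec` — Dirichlet for mRS outcome vectors and transition
#' rows, beta for single probabilities and utilities, gamma for costs and
#' hazard multipliers — and runs both strategies on each draw, recording the
#' incremental cost and QALYs. Scalar draws into probability vectors are
#' renormalized; vector draws replace the vector. Sampling is fully
#' deterministic given `seed` (parameters are drawn in lexicographic path
#' order within each iteration).
#'
#' @param params a `cea_parameters` object with a complete `psa_spec`.
#' @param n number of Monte Carlo iterations (the analysis convention is
#'   10,000).
#' @param seed integer RNG seed. The default, 20230905, is arbitrary but
#'   fixed for reproducibility.
#' @return a data.frame of class `psa_samples` with columns `draw`,
#'   `cost_DTAS`, `qaly_DTAS`, `cost_ITER`, `qaly_ITER`, `delta_cost`,
#'   `delta_qaly`; attributes `seed`, `intervention`, `comparator`,
#'   `thresholds`.
#' @seealso [ceac()], [plot_ce_plane()]
#' @export
sample_psa <- function(params, n = 10000, seed = 20230905) {
  stopifnot(n >= 1)
  if (length(params$psa_spec) == 0)
    stop("params$psa_spec is empty: nothing to sample", call. = FALSE)
  paths <- sort(names(params$psa_spec))
  set.seed(seed)
  out <- matrix(NA_real_, nrow = n, ncol = 6L)
  for (i in seq_len(n)) {
    p_i <- params
    for (path in paths) {
      v <- .psa_draw(params$psa_spec[[path]], path)
      p_i <- set_param(p_i, path, v, renormalize = length(v) == 1)
    }
    dtas <- run_strategy(p_i, "DTAS")
    iter <- run_strategy(p_i, "ITER")
    out[i, ] <- c(dtas$total_cost, dtas$total_qaly, iter$total_cost,
                  iter$total_qaly, dtas$total_cost - iter$total_cost,
                  dtas$total_qaly - iter$total_qaly)
  }
  out <- as.data.frame(out)
  names(out) <- c("cost_DTAS", "qaly_DTAS", "cost_ITER", "qaly_ITER",
                  "delta_cost", "delta_qaly")
  out <- cbind(draw = seq_len(n), out)
  attr(out, "seed") <- seed
  attr(out, "intervention") <- "DTAS"
  attr(out, "comparator") <- "ITER"
  attr(out, "thresholds") <- params$econ$thresholds
  class(out) <- c("psa_samples", class(out))
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For every willingness-to-pay value on the grid, the probability that the
#' intervention is cost-effective is the fraction of PSA draws with positive
#' net monetary benefit, `delta_qaly * lambda - delta_cost > 0` (ties count
#' for the comparator); with two strategies the comparator receives the
#' complement.
#'
#' @param samples a `psa_samples` data.frame from [sample_psa()].
#' @param grid willingness-to-pay grid; by default 0 to 150,000 per QALY in
#'   steps of 1,000, with the parameter set's decision thresholds inserted
#'   exactly.
#' @return a data.frame of class `ceac_curve` with columns `threshold`,
#'   `p_DTAS`, `p_ITER` (named after the actual intervention/comparator).
#' @export
ceac <- function(samples, grid = NULL) {
  stopifnot(nrow(samples) > 0)
  if (is.null(grid)) {
    grid <- sort(unique(c(seq(0, 150000, by = 1000),
                          attr(samples, "thresholds"))))
  }
  p_int <- vapply(grid, function(lam)
    mean(samples$delta_qaly * lam - samples$delta_cost > 0), numeric(1))
  out <- data.frame(threshold = grid, p_int = p_int, p_comp = 1 - p_int)
  names(out)[2:3] <- paste0("p_", c(attr(samples, "intervention") %||% "DTAS",
                                    attr(samples, "comparator") %||% "ITER"))
  class(out) <- c("ceac_curve", class(out))
  out
}

#' Run a complete scenario analysis
#'
#' Applies the scenario overrides (see [apply_scenario()]) and executes the
#' deterministic comparison, optionally followed by a tornado analysis and a
#' probabilistic sensitivity analysis with acceptability curves.
#'
#' @param params base-case `cea_parameters`.
#' @param scenario `"base"`, `"1"`, `"2"` or `"3"`.
#' @param psa_n PSA iterations (0 skips the PSA).
#' @param seed RNG seed for the PSA.
#' @param run_tornado logical; also run [tornado()] over the configured
#'   ranges.
#' @return a list of class `scenario_result` with elements `scenario`,
#'   `params`, `cea`, and (when requested) `tornado`, `psa`, `ceac`.
#' @export
run_scenario <- function(params, scenario = "base", psa_n = 0,
                         seed = 20230905, run_tornado = FALSE) {
  params <- apply_scenario(params, scenario)
  out <- list(scenario = as.character(scenario), params = params,
              cea = run_cea(params))
  if (isTRUE(run_tornado)) out$tornado <- tornado(params)
  if (psa_n > 0) {
    out$psa <- sample_psa(params, n = psa_n, seed = seed)
    out$ceac <- ceac(out$psa)
  }
  structure(out, class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result: scenario %s>\n", x$scenario))
  print(x$cea)
  if (!is.null(x$psa))
    cat(sprintf("  PSA: %d draws (seed %s)\n", nrow(x$psa),
                attr(x$psa, "seed")))
  if (!is.null(x$tornado))
    cat(sprintf("  tornado: %d parameters, widest '%s'\n", nrow(x$tornado),
                if (nrow(x$tornado)) x$tornado$parameter[1] else "-"))
  invisible(x)
}
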