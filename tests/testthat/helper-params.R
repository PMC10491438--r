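# Hand-built minimal parameter set for unit tests: near-trivial dynamics so
# expected values are computable by hand. Not a realistic parameterization.
toy_params <- function(p_lvo = 1, markov_years = 9, discount_cost = 0,
                       discount_qaly = 0, utilities = c(1, 1, 1, 1),
                       q0 = 0, hr = c(1, 1, 1, 1),
                       t90 = diag(5), t_annual = diag(5),
                       outcome_dtas = c(1, 0, 0, 0, 0),
                       outcome_iter = c(1, 0, 0, 0, 0),
                       annual_care = c(0, 0, 0, 0),
                       acute = c(DTAS = 0, ITER = 0),
                       diag_non_lvo = c(DTAS = 0, ITER = 0),
                       validate = FALSE) {
  st <- dtascea::health_states()
  liv <- dtascea::living_states()
  names(outcome_dtas) <- names(outcome_iter) <- st
  names(utilities) <- names(annual_care) <- names(hr) <- liv
  dtascea::cea_parameters(
    outcome90d = list(DTAS = outcome_dtas, ITER = outcome_iter),
    t90 = t90, t_annual = t_annual,
    mortality = list(age = 70:95, q0 = rep(q0, 26), hr = hr),
    utilities = utilities,
    costs = list(acute_lvo = acute, diag_non_lvo = diag_non_lvo,
                 annual_care = annual_care, currency = "EUR",
                 eur_to_usd = 1.1827),
    triage = list(p_lvo = p_lvo),
    econ = list(discount_cost = discount_cost, discount_qaly = discount_qaly,
                markov_years = markov_years),
    options = list(utility_order_check = FALSE),
    validate = validate
  )
}

# fabricated strategy_result for CEA algebra tests
fake_result <- function(strategy, cost, qaly) {
  structure(list(strategy = strategy, total_cost = cost, total_qaly = qaly,
                 cost_year1 = 0, qaly_year1 = 0,
                 trace = matrix(0, 1, 5)),
            class = "strategy_result")
}
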