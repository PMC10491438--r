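test_that("one-way analysis at a degenerate range returns the base ICER twice", {
  p <- example_parameters()
  base_icer <- run_cea(p)$icer
  v <- param_value(p, "costs.acute_lvo.DTAS")
  e <- one_way(p, "costs.acute_lvo.DTAS", v, v)
  expect_equal(e$icer_at_low, base_icer)
  expect_equal(e$icer_at_high, base_icer)
  expect_equal(e$spread, 0)
})

test_that("a parameter with no differential occupancy has zero spread", {
  # neither arm ever occupies MRS5 (no entry mass, identity transitions), so
  # its care cost cannot move the ICER: the spread is exactly zero
  p <- toy_params(outcome_dtas = c(0.5, 0.3, 0.15, 0, 0.05),
                  outcome_iter = c(0.3, 0.35, 0.25, 0, 0.1),
                  acute = c(DTAS = 2000, ITER = 1000),
                  annual_care = c(10, 20, 30, 40),
                  utilities = c(0.9, 0.6, 0.3, 0.1),
                  q0 = 0.05, p_lvo = 0.8)
  e <- one_way(p, "costs.annual_care.MRS5", 10, 80)
  expect_equal(e$spread, 0)
  # whereas a state the arms occupy differently does move the ICER
  e2 <- one_way(p, "costs.annual_care.MRS01", 5, 50)
  expect_gt(e2$spread, 0)
})

test_that("tornado entries are ordered by spread, widest first", {
  expect_equal(nrow(tornado(example_parameters(), ranges = list())), 0)

  p <- toy_params(outcome_dtas = c(0.5, 0.25, 0.15, 0.05, 0.05),
                  outcome_iter = c(0.3, 0.3, 0.2, 0.1, 0.1),
                  acute = c(DTAS = 2000, ITER = 1000),
                  annual_care = c(10, 20, 30, 40),
                  utilities = c(0.9, 0.6, 0.3, 0.1),
                  q0 = 0.05, p_lvo = 0.8)
  tor <- tornado(p, ranges = list(
    "costs.acute_lvo.DTAS" = c(1500, 2500),
    "costs.acute_lvo.ITER" = c(999.999, 1000.001),  # negligible spread
    "utilities.MRS01" = c(0.8, 1.0)))
  expect_s3_class(tor, "tornado_result")
  expect_equal(tor$spread, sort(tor$spread, decreasing = TRUE))
  expect_equal(tor$parameter[3], "costs.acute_lvo.ITER")
})

test_that("degenerate PSA with fixed distributions reproduces the base case", {
  p <- example_parameters()
  base <- run_cea(p)
  p$psa_spec <- list(
    "triage.p_lvo" = psa_fixed_spec(p$triage$p_lvo),
    "utilities.MRS01" = psa_fixed_spec(unname(p$utilities["MRS01"])))
  s <- sample_psa(p, n = 25, seed = 4)
  expect_equal(unique(s$delta_cost), base$delta_cost)
  expect_equal(unique(s$delta_qaly), base$delta_qaly)
})

test_that("PSA is reproducible from its seed and sensitive to it", {
  p <- example_parameters()
  s1 <- sample_psa(p, n = 40, seed = 123)
  s2 <- sample_psa(p, n = 40, seed = 123)
  s3 <- sample_psa(p, n = 40, seed = 124)
  expect_identical(s1, s2)
  expect_false(isTRUE(all.equal(s1$delta_cost, s3$delta_cost)))
})

test_that("PSA samplers match their declared moments", {
  set.seed(1)
  n <- 1e5
  spec_b <- psa_beta_spec(0.3, se = 0.05)
  draws <- replicate(n, dtascea:::.psa_draw(spec_b, "x"))
  m <- spec_b$shape1 / (spec_b$shape1 + spec_b$shape2)
  expect_equal(m, 0.3)
  expect_lt(abs(mean(draws) - m), 3 * stats::sd(draws) / sqrt(n))

  spec_g <- psa_gamma_spec(25000)
  gd <- stats::rgamma(n, shape = spec_g$shape, rate = spec_g$rate)
  expect_equal(spec_g$shape / spec_g$rate, 25000)
  expect_equal(sqrt(spec_g$shape) / spec_g$rate, 5000)  # se = 20% of mean
  expect_lt(abs(mean(gd) - 25000), 3 * stats::sd(gd) / sqrt(n))

  dir <- dtascea:::.rdirichlet(n, c(8, 4, 2, 1, 1))
  expect_equal(unname(rowSums(dir)), rep(1, n), tolerance = 1e-12)
  expect_equal(colMeans(dir), c(8, 4, 2, 1, 1) / 16, tolerance = 0.005)

  expect_error(dtascea:::.psa_draw(list(family = "dirichlet",
                                        alpha = c(-1, 2)), "x"), "invalid")
  expect_error(dtascea:::.psa_draw(list(family = "nope"), "x"))
})

test_that("CEAC probabilities complement each other and honour the NMB rule", {
  p <- example_parameters()
  s <- sample_psa(p, n = 400, seed = 7)
  cv <- ceac(s, grid = seq(0, 120000, by = 5000))
  expect_equal(cv$p_DTAS + cv$p_ITER, rep(1, nrow(cv)))
  expect_true(all(cv$p_DTAS >= 0 & cv$p_DTAS <= 1))
  # at lambda = 0 the acceptance probability is the cost-saving fraction
  expect_equal(cv$p_DTAS[cv$threshold == 0], mean(s$delta_cost < 0))

  # a single-atom sample in the NE quadrant yields a step at its ICER
  atom <- s[1, ]
  atom$delta_cost <- 10000; atom$delta_qaly <- 0.5  # ICER 20,000
  cv2 <- ceac(atom, grid = c(0, 19999, 20000, 20001, 50000))
  expect_equal(cv2$p_DTAS, c(0, 0, 0, 1, 1))  # tie at 20,000 -> comparator

  # with all delta_qaly > 0 the curve is monotone non-decreasing
  pos <- s[s$delta_qaly > 0, ]
  cv3 <- ceac(pos, grid = seq(0, 150000, by = 1000))
  expect_true(all(diff(cv3$p_DTAS) >= 0))
})

test_that("CEAC curves are stable in the number of draws", {
  p <- example_parameters()
  a <- ceac(sample_psa(p, n = 2500, seed = 11))
  b <- ceac(sample_psa(p, n = 5000, seed = 12))
  for (thr in p$econ$thresholds) {
    expect_lt(abs(a$p_DTAS[a$threshold == thr] -
                    b$p_DTAS[b$threshold == thr]), 0.02)
  }
})

test_that("scenario runs apply exactly their documented overrides", {
  p <- example_parameters()
  base <- run_scenario(p, "base")
  expect_equal(base$cea$delta_cost, run_cea(p)$delta_cost)

  s2 <- run_scenario(p, "2")
  expect_equal(s2$params$triage$p_lvo, 0.12)
  keep <- setdiff(names(unclass(p)), "triage")
  expect_equal(unclass(s2$params)[keep], unclass(p)[keep])

  s3 <- run_scenario(p, "3")
  expect_equal(nrow(s3$cea$results$DTAS$trace), 5L)  # 1 + 4-year horizon

  expect_error(run_scenario(p, "9"), "unknown scenario")

  full <- run_scenario(p, "1", psa_n = 50, seed = 2, run_tornado = TRUE)
  expect_s3_class(full$psa, "psa_samples")
  expect_s3_class(full$ceac, "ceac_curve")
  expect_s3_class(full$tornado, "tornado_result")
  expect_equal(nrow(full$psa), 50)
})
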