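test_that("base-case LVO probability comes from trial counts", {
  expect_equal(base_p_lvo_from_trial(174, 147), 147 / 174)
  expect_equal(base_p_lvo_from_trial(100, 100), 1)
  expect_error(base_p_lvo_from_trial(200, 0))
  expect_error(base_p_lvo_from_trial(0, 0))
  expect_error(base_p_lvo_from_trial(100, 101))
})

test_that("packaged parameter file loads and validates", {
  p <- example_parameters()
  expect_s3_class(p, "cea_parameters")
  expect_equal(p$triage$p_lvo, 147 / 174)
  expect_equal(p$econ$discount_cost, 0.04)
  expect_equal(p$econ$discount_qaly, 0.015)
  expect_equal(p$econ$thresholds, c(50000, 80000))
  expect_equal(p$econ$entry_age, 74)
  expect_equal(p$econ$markov_years, 9)
  expect_equal(p$costs$eur_to_usd, 1.1827)
})

test_that("write/load round-trips to an equal parameter set", {
  for (p in list(example_parameters(),
                 generate_parameter_set(synthetic_spec(seed = 11)))) {
    f <- withr::local_tempfile(fileext = ".json")
    write_parameters(p, f)
    back <- load_parameters(f)
    keep <- setdiff(names(unclass(p)), "sources")
    expect_equal(unclass(back)[keep], unclass(p)[keep], tolerance = 0)
  }
})

test_that("scenario overrides touch only the documented keys and are idempotent", {
  base <- example_parameters()
  s1 <- apply_scenario(base, "1")
  s2 <- apply_scenario(base, 2)
  s3 <- apply_scenario(base, "3")
  expect_equal(s1$triage$p_lvo, 0.42)
  expect_equal(s2$triage$p_lvo, 0.12)
  expect_equal(s3$econ$markov_years, 4)
  # everything else untouched
  strip <- function(p, drop) { q <- unclass(p); q[["triage"]] <- NULL
    q[["econ"]] <- NULL; q }
  expect_equal(strip(s1), strip(base))
  expect_equal(s1$econ, base$econ)
  expect_equal(s3$triage, base$triage)
  # idempotent
  expect_equal(apply_scenario(s1, "1"), s1)
  expect_equal(apply_scenario(base, "base"), base)
  expect_error(apply_scenario(base, "4"), "unknown scenario")
})

test_that("validation rejects each invariant violation and reports them together", {
  ok <- example_parameters()

  broken_row <- ok
  broken_row$t_annual["MRS23", "MRS23"] <- broken_row$t_annual["MRS23", "MRS23"] - 0.02
  expect_error(validate_parameters(broken_row), "row MRS23")

  bad_dead <- ok
  bad_dead$t90["DEAD", ] <- c(0.1, 0, 0, 0, 0.9)
  expect_error(validate_parameters(bad_dead), "absorbing")

  bad_out <- ok
  bad_out$outcome90d$DTAS["MRS01"] <- bad_out$outcome90d$DTAS["MRS01"] + 0.05
  expect_error(validate_parameters(bad_out), "outcome90d.DTAS")

  bad_u <- ok
  bad_u$utilities["MRS5"] <- 1.5
  expect_error(validate_parameters(bad_u), "utilities")

  unordered_u <- ok
  unordered_u$utilities <- c(MRS01 = 0.3, MRS23 = 0.6, MRS4 = 0.2,
                             MRS5 = 0.1)
  expect_error(validate_parameters(unordered_u), "u\\(MRS01\\)")
  unordered_u$options$utility_order_check <- FALSE
  expect_silent(validate_parameters(unordered_u))

  bad_cost <- ok
  bad_cost$costs$annual_care["MRS4"] <- -5
  expect_error(validate_parameters(bad_cost), "negative cost")

  bad_plvo <- ok
  bad_plvo$triage$p_lvo <- 0
  expect_error(validate_parameters(bad_plvo), "p_lvo")

  bad_disc <- ok
  bad_disc$econ$discount_cost <- 1
  expect_error(validate_parameters(bad_disc), "discount_cost")

  bad_table <- ok
  bad_table$mortality$age <- 74:78
  bad_table$mortality$q0 <- bad_table$mortality$q0[1:5]
  expect_error(validate_parameters(bad_table), "life table")

  bad_hr <- ok
  bad_hr$mortality$hr["MRS4"] <- -1
  expect_error(validate_parameters(bad_hr), "hazard")

  bad_path <- ok
  bad_path$owsa_ranges <- list("no.such.param" = c(0, 1))
  expect_error(validate_parameters(bad_path), "no.such.param")

  # all violations are collected, not just the first
  multi <- ok
  multi$triage$p_lvo <- 0
  multi$costs$annual_care["MRS4"] <- -5
  err <- tryCatch(validate_parameters(multi), error = identity)
  expect_s3_class(err, "dtascea_validation_error")
  expect_match(conditionMessage(err), "2 violations")
  expect_match(conditionMessage(err), "p_lvo")
  expect_match(conditionMessage(err), "annual_care")
})

test_that("parse failures and scenario loading are reported from the loader", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not json", f)
  expect_error(load_parameters(f), "cannot parse")
  expect_error(load_parameters("/nonexistent/file.json"), "not found")

  src <- system.file("extdata", "params_synthetic_base.json",
                     package = "dtascea")
  expect_equal(load_parameters(src, scenario = "1")$triage$p_lvo, 0.42)
  expect_equal(load_parameters(src, scenario = 3)$econ$markov_years, 4)
})

test_that("parameter paths resolve scalars, vectors and matrix cells", {
  p <- example_parameters()
  expect_equal(param_value(p, "triage.p_lvo"), 147 / 174)
  expect_equal(param_value(p, "outcome90d.DTAS.MRS01"), 0.2838)
  expect_equal(param_value(p, "utilities.MRS23"), unname(p$utilities["MRS23"]))
  expect_equal(param_value(p, "t_annual.MRS23.MRS01"),
               p$t_annual["MRS23", "MRS01"])
  expect_equal(param_value(p, "outcome90d.ITER"), p$outcome90d$ITER)
  expect_equal(param_value(p, "mortality.hr.MRS5"),
               unname(p$mortality$hr["MRS5"]))
  expect_error(param_value(p, "no.such.path"), "unknown parameter path")
})

test_that("set_param renormalizes probability-vector components", {
  p <- example_parameters()
  old <- p$outcome90d$DTAS
  q <- set_param(p, "outcome90d.DTAS.MRS01", 0.5)
  v <- q$outcome90d$DTAS
  expect_equal(sum(v), 1)
  expect_equal(unname(v["MRS01"]), 0.5)
  # siblings rescaled proportionally
  expect_equal(unname(v[-1] / old[-1]),
               rep((1 - 0.5) / (1 - old[["MRS01"]]), 4))

  # DEAD component varied: living states rescaled symmetrically
  q2 <- set_param(p, "outcome90d.ITER.DEAD", 0.4)
  v2 <- q2$outcome90d$ITER
  expect_equal(sum(v2), 1)
  expect_equal(unname(v2["DEAD"]), 0.4)

  # matrix row component
  q3 <- set_param(p, "t_annual.MRS23.MRS01", 0.2)
  expect_equal(sum(q3$t_annual["MRS23", ]), 1)
  expect_equal(q3$t_annual["MRS23", "MRS01"], 0.2)

  # non-simplex scalars set plainly
  q4 <- set_param(p, "costs.annual_care.MRS4", 30000)
  expect_equal(unname(q4$costs$annual_care["MRS4"]), 30000)
  expect_equal(q4$costs$annual_care[-3], p$costs$annual_care[-3])

  # whole-vector replacement
  nv <- c(0.2, 0.2, 0.2, 0.2, 0.2)
  q5 <- set_param(p, "outcome90d.DTAS", nv)
  expect_equal(unname(q5$outcome90d$DTAS), nv)

  expect_error(set_param(p, "outcome90d.DTAS.MRS01", 1.2), "outside")
  expect_error(set_param(p, "outcome90d.DTAS.MRS01", -0.1), "outside")
})
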