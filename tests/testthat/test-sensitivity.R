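test_that("fixed parameter sets sample to their base values", {
  params <- list(param_fixed("a", 1.5), param_fixed("b", 0.3))
  d <- sample_parameters(params, 5)
  expect_equal(d$a, rep(1.5, 5))
  expect_equal(d$b, rep(0.3, 5))
})

test_that("sampled distributions match their analytic means at n = 10,000", {
  n <- 10000
  params <- list(
    param_normal("p", mean = 0.261, sd = 0.052, lower = 0, upper = 1),
    param_beta("u", shape1 = 623.29, shape2 = 254.58),
    param_gamma_cost("c", base = 5866, fx = 157.2, shape = 25))
  set.seed(123)
  d <- sample_parameters(params, n)

  # analytic means and standard errors
  expect_lt(abs(mean(d$p) - 0.261), 3 * 0.052 / sqrt(n))
  mu_u <- 623.29 / (623.29 + 254.58)
  sd_u <- sqrt(mu_u * (1 - mu_u) / (623.29 + 254.58 + 1))
  expect_lt(abs(mean(d$u) - mu_u), 3 * sd_u / sqrt(n))
  expect_lt(abs(mean(d$c) - 5866), 3 * (5866 / sqrt(25)) / sqrt(n))
  # CV-20% design of the cost gammas
  expect_equal(sd(d$c) / mean(d$c), 0.2, tolerance = 0.05)
})

test_that("truncated normal draws respect their bounds", {
  params <- list(param_normal("x", mean = 0.05, sd = 0.2, lower = 0, upper = 1))
  set.seed(5)
  d <- sample_parameters(params, 5000)
  expect_true(all(d$x >= 0 & d$x <= 1))
  expect_error(sample_parameters(list(new_param("x", "cauchy", 0)), 2),
               "unknown distribution")
})

test_that("degenerate PSA reproduces the deterministic pipeline exactly", {
  cfg <- toy_config()
  base <- base_sensitivity_params(cfg)
  params <- lapply(names(base), function(nm) param_fixed(nm, base[[nm]]))
  psa <- run_psa(cfg, n_iter = 10, seed = 99, params = params)
  det <- evaluate_parameter_set(cfg, base)

  expect_true(all(psa$draws$threshold_payer == det$threshold_payer))
  s <- psa$summary
  expect_equal(s$p5[s$quantity == "threshold_payer"], det$threshold_payer)
  expect_equal(s$p95[s$quantity == "threshold_payer"], det$threshold_payer)
  expect_equal(s$p5[s$quantity == "delta_qaly"], det$delta_qaly)
})

test_that("PSA output is reproducible for a fixed seed", {
  cfg <- toy_config()
  p1 <- run_psa(cfg, n_iter = 50, seed = 42)
  p2 <- run_psa(cfg, n_iter = 50, seed = 42)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$summary, p2$summary)
  p3 <- run_psa(cfg, n_iter = 50, seed = 43)
  expect_false(identical(p1$draws, p3$draws))
})

test_that("PSA percentiles are order statistics of the stored draws", {
  cfg <- toy_config()
  psa <- run_psa(cfg, n_iter = 100, seed = 7)
  s <- psa$summary
  expect_equal(s$p5[s$quantity == "delta_qaly"],
               unname(quantile(psa$draws$delta_qaly, 0.05)))
  expect_equal(s$p95[s$quantity == "threshold_payer_ltc"],
               unname(quantile(psa$draws$threshold_payer_ltc, 0.95)))
  expect_true(all(s$p5 <= s$p95))
})

test_that("tornado records are sorted by span and bracket-validated", {
  cfg <- toy_config()
  d <- run_dsa(cfg)
  expect_s3_class(d, "dsa_result")
  expect_true(all(diff(d$span) <= 0))
  expect_true(all(d$span >= 0))

  # degenerate range pins both ends to the base-case threshold
  base_rr <- cfg$efficacy$risk_ratio
  d0 <- run_dsa(cfg, ranges = list(risk_ratio = c(base_rr, base_rr)))
  expect_equal(d0$threshold_low, attr(d0, "threshold_base"))
  expect_equal(d0$threshold_high, attr(d0, "threshold_base"))

  expect_error(run_dsa(cfg, ranges = list(risk_ratio = c(1.5, 2))),
               "does not bracket")
  expect_error(run_dsa(cfg, ranges = list(u_disabled = c(0.4, 1.2))),
               "unit interval")
  expect_error(run_dsa(cfg, ranges = list(nonsense = c(0, 1))), "unknown parameter")
})

test_that("one-way cost variation matches a direct two-point re-evaluation", {
  cfg <- toy_config()
  d <- run_dsa(cfg, ranges = list(hosp_disabled = c(1600, 2400)))

  # oracle: rebuild the two evaluations from package primitives
  oracle_threshold <- function(hosp_dis) {
    s <- config_settings(cfg)
    init_t <- build_initial_distribution(
      min(cfg$efficacy$p_control_functional * cfg$efficacy$risk_ratio,
          1 - cfg$efficacy$p_dead), cfg$efficacy$p_dead)
    init_c <- build_initial_distribution(cfg$efficacy$p_control_functional,
                                         cfg$efficacy$p_dead)
    sched <- ltc_schedule(cfg$ltc_levels, cfg$ltc_mapping, cfg$mix_weights)
    costs <- state_costs(c(cfg$hospitalization_by_state[1], hosp_dis,
                           cfg$hospitalization_by_state[3]),
                         c(ltc_monthly_cost("functional", sched),
                           ltc_monthly_cost("disabled", sched), 0))
    u <- utility_set(cfg$utilities$functional, cfg$utilities$disabled)
    arm <- function(init) {
      accumulate_outcomes(run_cohort(init, cfg$transition_matrix,
                                     s$horizon_months, s$start_month),
                          u, costs, s)
    }
    cea <- compare_arms(arm(init_t), arm(init_c), s)
    cea$threshold_payer
  }
  expect_equal(d$threshold_low, oracle_threshold(1600), tolerance = 1e-10)
  expect_equal(d$threshold_high, oracle_threshold(2400), tolerance = 1e-10)
  # treated arm holds fewer disabled patients, so dearer disability care
  # favors the therapy: threshold grows with the cost
  expect_gte(d$threshold_high, d$threshold_low)
})
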