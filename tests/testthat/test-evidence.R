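test_that("pooled proportions reproduce the trial-count arithmetic", {
  expect_equal(pooled_proportion(16, 457), 16 / 457)
  expect_equal(round(100 * pooled_proportion(16, 457), 1), 3.5)
  expect_equal(round(100 * pooled_proportion(16, 403), 1), 4.0)
  expect_equal(pooled_proportion(0, 100), 0)
  expect_error(pooled_proportion(5, 0), "positive")
  expect_error(pooled_proportion(-1, 10), "\\[0, total\\]")
  expect_error(pooled_proportion(11, 10), "\\[0, total\\]")
})

test_that("residual disability is the remainder after independence and death", {
  expect_equal(residual_disabled(0.326, 0.035), 0.639)
  expect_equal(residual_disabled(0.214, 0.037), 0.749)
  expect_equal(residual_disabled(1, 0), 0)
  expect_error(residual_disabled(0.7, 0.4), "exceeds 1")
})

test_that("initial distributions are valid and sum to one across a grid", {
  d <- build_initial_distribution(0.326, 0.035)
  expect_s3_class(d, "initial_distribution")
  expect_equal(unname(d[]), c(0.326, 0.639, 0.035))
  expect_equal(unname(build_initial_distribution(0.261, 0.035)[]),
               c(0.261, 0.704, 0.035))
  expect_equal(unname(build_initial_distribution(0, 1)[]), c(0, 0, 1))

  for (pf in seq(0, 1, by = 0.1)) {
    for (pd in seq(0, 1 - pf, by = 0.1)) {
      expect_equal(sum(build_initial_distribution(pf, pd)), 1)
    }
  }
  expect_error(initial_distribution(0.5, 0.6, 0.2), "sum to 1")
})

test_that("risk-ratio application is clamped and monotone", {
  expect_equal(apply_risk_ratio(0.261, 1.31), 0.34191)
  expect_equal(apply_risk_ratio(0.261, 1.0), 0.261)
  expect_equal(apply_risk_ratio(0.9, 1.5), 1)

  ps <- seq(0.05, 0.6, by = 0.05)
  rrs <- seq(0.5, 1.6, by = 0.1)
  for (rr in rrs) expect_true(all(diff(apply_risk_ratio(ps, rr)) > 0))
  for (p in ps) {
    vals <- vapply(rrs, function(r) apply_risk_ratio(p, r), numeric(1))
    expect_true(all(diff(vals) > 0))
  }
  expect_error(apply_risk_ratio(0.3, -1), "positive")
})

test_that("single-study and replicated-study pooling give the plain risk ratio", {
  one <- data.frame(study_id = "a", treated_events = 30, treated_total = 100,
                    control_events = 20, control_total = 100)
  m1 <- meta_risk_ratio(one)
  expect_equal(m1$rr, 1.5)
  expect_equal(m1$model, "fixed")
  expect_equal(m1$i_squared, 0)

  for (k in c(2, 5)) {
    mk <- meta_risk_ratio(one[rep(1, k), ])
    expect_equal(mk$rr, 1.5)
    expect_equal(mk$i_squared, 0)
    expect_equal(mk$model, "fixed")
  }
})

test_that("fixed-effect pooling agrees with the inverse-variance oracle and metafor", {
  tab <- data.frame(
    study_id = c("a", "b", "c"),
    treated_events = c(30, 18, 60), treated_total = c(100, 50, 180),
    control_events = c(20, 15, 41), control_total = c(100, 50, 190))
  m <- meta_risk_ratio(tab, i2_threshold = 100)  # force fixed-effect reporting
  oracle <- iv_fixed_oracle(tab)
  # the two fixed-effect estimators are distinct but close on these tables
  expect_equal(m$rr, oracle$rr, tolerance = 1e-2)
  expect_equal(m$q, oracle$q, tolerance = 1e-6)
  expect_equal(m$i_squared, oracle$i2, tolerance = 1e-6)

  skip_if_not_installed("metafor")
  mh <- metafor::rma.mh(ai = treated_events, n1i = treated_total,
                        ci = control_events, n2i = control_total,
                        data = tab, measure = "RR",
                        correct = FALSE, add = 0, to = "none")
  expect_equal(m$rr, exp(as.numeric(mh$beta)), tolerance = 1e-10)
  expect_equal(log(m$ci_high) - log(m$ci_low),
               2 * stats::qnorm(0.975) * mh$se, tolerance = 1e-10)
})

test_that("heterogeneous tables switch to DerSimonian-Laird random effects", {
  tab <- data.frame(
    study_id = c("a", "b", "c"),
    treated_events = c(60, 10, 45), treated_total = c(100, 100, 100),
    control_events = c(20, 30, 25), control_total = c(100, 100, 100))
  m <- meta_risk_ratio(tab)
  expect_gt(m$i_squared, 25)
  expect_equal(m$model, "random")
  expect_gt(m$tau2, 0)

  skip_if_not_installed("metafor")
  dl <- metafor::rma(ai = treated_events, n1i = treated_total,
                     ci = control_events, n2i = control_total,
                     data = tab, measure = "RR", method = "DL",
                     add = 0, to = "none")
  expect_equal(m$rr, exp(as.numeric(dl$beta)), tolerance = 1e-10)
  expect_equal(m$tau2, dl$tau2, tolerance = 1e-10)
  expect_equal(m$ci_low, exp(as.numeric(dl$beta) - 1.959964 * dl$se),
               tolerance = 1e-6)
})

test_that("zero cells get the continuity correction; all-zero tables are rejected", {
  tab <- data.frame(study_id = c("a", "b"),
                    treated_events = c(0, 12), treated_total = c(50, 60),
                    control_events = c(4, 9), control_total = c(50, 60))
  m <- meta_risk_ratio(tab)
  expect_true(is.finite(m$rr) && m$rr > 0)
  expect_true(is.finite(m$ci_low))

  allzero <- data.frame(study_id = "a", treated_events = 0, treated_total = 50,
                        control_events = 0, control_total = 50)
  expect_error(meta_risk_ratio(allzero), "zero events in both arms")
})

test_that("trial tables round-trip through CSV and are validated", {
  path <- system.file("extdata", "synthetic_trials.csv", package = "sctcea")
  tab <- read_trial_table(path)
  expect_equal(nrow(tab), 6)
  m <- meta_risk_ratio(tab)
  expect_true(m$rr > 1)

  bad <- tab
  bad$control_total[1] <- 0
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_trial_table(tmp), "total <= 0")
  expect_error(meta_risk_ratio(tab[, -1]), "study_id")
})

test_that("pooled confidence intervals cover the true risk ratio at ~95%", {
  true_rr <- 1.31
  n_rep <- 500
  covered <- vapply(seq_len(n_rep), function(seed) {
    tab <- generate_trials(5, 150, base_risk = 0.25, true_rr = true_rr,
                           between_study_sd = 0, seed = seed)
    m <- meta_risk_ratio(tab)
    m$ci_low <= true_rr && true_rr <= m$ci_high
  }, logical(1))
  expect_gt(mean(covered), 0.92)
  expect_lt(mean(covered), 0.98)
})
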