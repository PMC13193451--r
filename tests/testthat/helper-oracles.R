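# Independent oracles kept deliberately separate from the package's own
# code paths.

# matrix-power oracle: occupancy after k cycles as init %*% m^k
matpow <- function(m, k) {
  out <- diag(nrow(m))
  for (i in seq_len(k)) out <- out %*% m
  out
}

occupancy_by_power <- function(init, m, k) {
  as.numeric(matrix(as.numeric(init), nrow = 1) %*% matpow(unclass(m), k))
}

# brute-force inverse-variance meta-analysis on the log-RR scale
# (fixed effect), written directly from the textbook formulas
iv_fixed_oracle <- function(tab) {
  a <- tab$treated_events; n1 <- tab$treated_total
  c_ <- tab$control_events; n2 <- tab$control_total
  zero <- a == 0 | c_ == 0 | a == n1 | c_ == n2
  a <- a + 0.5 * zero; c_ <- c_ + 0.5 * zero
  n1 <- n1 + zero; n2 <- n2 + zero
  y <- log(a / n1) - log(c_ / n2)
  v <- 1 / a - 1 / n1 + 1 / c_ - 1 / n2
  mu <- sum(y / v) / sum(1 / v)
  se <- sqrt(1 / sum(1 / v))
  q <- sum((y - mu)^2 / v)
  list(rr = exp(mu), se = se, q = q,
       i2 = if (nrow(tab) == 1 || q <= nrow(tab) - 1) 0 else
         100 * (q - (nrow(tab) - 1)) / q)
}

# toy configuration: small, fully synthetic, fast to evaluate
toy_config <- function(transition = NULL, horizon = 24) {
  if (is.null(transition)) {
    transition <- list(c(0.9, 0.08, 0.02), c(0.05, 0.9, 0.05), c(0, 0, 1))
  }
  validate_config(list(
    scenarios = list(
      base = list(treated = list(p_functional = 0.4, p_dead = 0.1),
                  control = list(p_functional = 0.3, p_dead = 0.1)),
      same = list(treated = list(p_functional = 0.3, p_dead = 0.1),
                  control = list(p_functional = 0.3, p_dead = 0.1))),
    efficacy = list(p_control_functional = 0.3, risk_ratio = 1.2, p_dead = 0.1),
    utilities = list(functional = 0.8, disabled = 0.4, dead = 0),
    economics = list(discount_rate = 0.02, horizon_months = horizon,
                     start_month = 4, fx_jpy_per_usd = 157.2,
                     reference_icer_jpy = 5e6),
    hospitalization_by_state = c(1000, 2000, 1500),
    mix_weights = list(functional = c(1, 1, 1), disabled = c(1, 1, 1)),
    ltc_levels = list(tier_a = 100, tier_b = 300),
    ltc_mapping = list(
      mrs_1 = list(users = 0, levels = list(tier_a = 1)),
      mrs_2 = list(users = 0.5, levels = list(tier_a = 1)),
      mrs_3 = list(users = 1, levels = list(tier_a = 0.5, tier_b = 0.5)),
      mrs_4 = list(users = 1, levels = list(tier_b = 1)),
      mrs_5 = list(users = 1, levels = list(tier_b = 1))),
    transition_matrix = transition,
    dsa = list(risk_ratio = c(1.0, 1.4), hosp_disabled = c(1600, 2400)),
    psa = list(risk_ratio = list(kind = "normal", mean = 1.2, sd = 0.1))
  ))
}
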