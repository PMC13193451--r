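# Sensitivity-analysis pipeline. Both the one-way deterministic analysis
# and the probabilistic analysis re-run the full model per evaluation with
# the treated arm derived through the multiplicative efficacy pathway
# (p_treated = min(1 - p_dead, p_control * RR)); the scenario base cases use
# the observed pooled proportions instead.

#' Parameter sampling specifications
#'
#' Constructors for the per-parameter distributions of the probabilistic
#' sensitivity analysis. `param_gamma_cost` parameterizes a cost in USD as
#' gamma with the given shape and rate `shape / (mean * fx)` per JPY, so the
#' distribution mean equals the base-case cost and the coefficient of
#' variation is `1 / sqrt(shape)` (20% at the default shape 25).
#'
#' @param name Parameter id.
#' @param base Base-case value (the value a degenerate draw returns).
#' @param mean,sd Normal mean and standard deviation.
#' @param lower,upper Truncation bounds for normal draws (resampling).
#' @param shape1,shape2 Beta shape parameters.
#' @param fx Exchange rate (JPY per USD) used to express the gamma rate in
#'   JPY, matching how the cost distributions are tabulated.
#' @param shape Gamma shape parameter.
#' @return A `param_spec` list.
#' @export
param_fixed <- function(name, base) {
  new_param(name, "fixed", base)
}

#' @rdname param_fixed
#' @export
param_normal <- function(name, mean, sd, base = mean, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  new_param(name, "normal", base, mean = mean, sd = sd, lower = lower, upper = upper)
}

#' @rdname param_fixed
#' @export
param_beta <- function(name, shape1, shape2, base = shape1 / (shape1 + shape2)) {
  if (shape1 <= 0 || shape2 <= 0) {
    stop("beta shape parameters must be positive", call. = FALSE)
  }
  new_param(name, "beta", base, shape1 = shape1, shape2 = shape2)
}

#' @rdname param_fixed
#' @export
param_gamma_cost <- function(name, base, fx, shape = 25) {
  if (shape <= 0) stop("`shape` must be positive", call. = FALSE)
  if (base <= 0) stop("`base` must be positive for a gamma cost", call. = FALSE)
  new_param(name, "gamma", base, shape = shape,
            rate_jpy = shape / (base * fx), fx = fx)
}

new_param <- function(name, kind, base, ...) {
  structure(list(name = name, kind = kind, base = base, ...),
            class = "param_spec")
}

#' Draw parameter sets
#'
#' Jointly samples `n` independent draws of every parameter, consuming the
#' current random-number stream parameter by parameter in the order given
#' (the documented order of reproducibility). Truncated normals are drawn
#' by resampling out-of-range values; `fixed` parameters return their base
#' value.
#'
#' @param params List of `param_spec` objects.
#' @param n Number of joint draws.
#' @return A data frame with `n` rows and one column per parameter.
#' @export
sample_parameters <- function(params, n = 1) {
  draws <- lapply(params, function(p) {
    switch(p$kind,
      fixed = rep(p$base, n),
      normal = {
        x <- stats::rnorm(n, p$mean, p$sd)
        bad <- which(x < p$lower | x > p$upper)
        while (length(bad) > 0) {
          x[bad] <- stats::rnorm(length(bad), p$mean, p$sd)
          bad <- bad[x[bad] < p$lower | x[bad] > p$upper]
        }
        x
      },
      beta = stats::rbeta(n, p$shape1, p$shape2),
      gamma = stats::rgamma(n, shape = p$shape, rate = p$rate_jpy) / p$fx,
      stop(sprintf("unknown distribution kind: %s", p$kind), call. = FALSE)
    )
  })
  names(draws) <- vapply(params, `[[`, character(1), "name")
  as.data.frame(draws)
}

# named base-case values of every sensitivity parameter, in sampling order
base_sensitivity_params <- function(config) {
  lv <- config$ltc_levels
  c(list(
    p_control_functional = config$efficacy$p_control_functional,
    risk_ratio = config$efficacy$risk_ratio,
    p_dead = config$efficacy$p_dead,
    u_functional = config$utilities$functional,
    u_disabled = config$utilities$disabled,
    hosp_functional = config$hospitalization_by_state[[1]],
    hosp_disabled = config$hospitalization_by_state[[2]],
    hosp_dead = config$hospitalization_by_state[[3]]),
    stats::setNames(lapply(names(lv), function(k) lv[[k]]),
                    paste0("ltc_", names(lv))),
    list(discount_rate = config$economics$discount_rate))
}

#' Default distribution set for the probabilistic sensitivity analysis
#'
#' Builds the parameter distributions from the configuration's `psa`
#' section: truncated normals for the efficacy proportions and the risk
#' ratio, betas for the utilities, and CV-20% gammas (shape 25, rate in
#' JPY) for every cost. Parameters without a `psa` entry are held fixed.
#'
#' @param config A loaded configuration (see [load_config()]).
#' @return A list of `param_spec` objects in the documented sampling order.
#' @export
psa_parameters <- function(config) {
  base <- base_sensitivity_params(config)
  fx <- config$economics$fx_jpy_per_usd
  spec <- config$psa
  lapply(names(base), function(nm) {
    s <- spec[[nm]]
    if (is.null(s)) return(param_fixed(nm, base[[nm]]))
    switch(s$kind,
      fixed = param_fixed(nm, base[[nm]]),
      normal = {
        lim <- if (nm == "risk_ratio") c(1e-12, Inf) else c(0, 1)
        param_normal(nm, s$mean, s$sd, base = base[[nm]],
                     lower = lim[1], upper = lim[2])
      },
      beta = param_beta(nm, s$shape1, s$shape2, base = base[[nm]]),
      gamma = param_gamma_cost(nm, base[[nm]], fx,
                               shape = if (is.null(s$shape)) 25 else s$shape),
      stop(sprintf("psa: unknown distribution kind `%s` for %s", s$kind, nm),
           call. = FALSE))
  })
}

# one full-model evaluation at a named parameter set (list or 1-row df)
evaluate_parameter_set <- function(config, theta) {
  theta <- as.list(theta)
  eco <- config$economics
  settings <- econ_settings(discount_rate = theta$discount_rate,
                            horizon_months = eco$horizon_months,
                            start_month = eco$start_month,
                            fx_jpy_per_usd = eco$fx_jpy_per_usd,
                            reference_icer_jpy = eco$reference_icer_jpy)

  p_treated <- min(apply_risk_ratio(theta$p_control_functional, theta$risk_ratio),
                   1 - theta$p_dead)
  init_t <- build_initial_distribution(p_treated, theta$p_dead)
  init_c <- build_initial_distribution(theta$p_control_functional, theta$p_dead)

  utilities <- utility_set(theta$u_functional, theta$u_disabled)

  levels <- unlist(theta[paste0("ltc_", names(config$ltc_levels))])
  names(levels) <- names(config$ltc_levels)
  schedule <- ltc_schedule(levels, config$ltc_mapping, config$mix_weights)
  costs <- state_costs(
    hospitalization = c(theta$hosp_functional, theta$hosp_disabled, theta$hosp_dead),
    ltc_monthly = c(ltc_monthly_cost("functional", schedule),
                    ltc_monthly_cost("disabled", schedule), 0))

  m <- config$transition_matrix
  run_arm <- function(init) {
    accumulate_outcomes(run_cohort(init, m, eco$horizon_months, eco$start_month),
                        utilities, costs, settings)
  }
  cea <- compare_arms(run_arm(init_t), run_arm(init_c), settings)

  data.frame(delta_medical = cea$delta_medical,
             delta_ltc = cea$delta_ltc,
             delta_total = cea$delta_total,
             delta_qaly = cea$delta_qaly,
             finite_price = cea$finite_price,
             threshold_payer = threshold_price_value(cea$delta_medical,
                                                     cea$delta_qaly, settings),
             threshold_payer_ltc = threshold_price_value(cea$delta_total,
                                                         cea$delta_qaly, settings))
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full pipeline twice per parameter, once at each end of its
#' range with every other parameter at base, and records the resulting
#' threshold therapy prices. Records are sorted by descending span so they
#' can be drawn directly as a tornado diagram.
#'
#' @param config A loaded configuration.
#' @param ranges Named list of `c(low, high)` ranges; defaults to the
#'   configuration's `dsa` section. Each range must bracket (or equal) the
#'   parameter's base value.
#' @param perspective `"payer"` (medical costs only) or `"payer_plus_ltc"`.
#' @return A data frame of class `dsa_result` with columns `name`,
#'   `low_value`, `high_value`, `threshold_low`, `threshold_high`, `span`,
#'   sorted by non-increasing `span`; the base-case threshold is attached
#'   as attribute `threshold_base`.
#' @export
run_dsa <- function(config, ranges = NULL,
                    perspective = c("payer", "payer_plus_ltc")) {
  perspective <- match.arg(perspective)
  col <- if (perspective == "payer") "threshold_payer" else "threshold_payer_ltc"
  if (is.null(ranges)) ranges <- config$dsa
  if (is.null(ranges) || length(ranges) == 0) {
    stop("no DSA ranges supplied (config has no `dsa` section)", call. = FALSE)
  }
  base <- base_sensitivity_params(config)
  unknown <- setdiff(names(ranges), names(base))
  if (length(unknown) > 0) {
    stop(sprintf("dsa: unknown parameter(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }

  records <- lapply(names(ranges), function(nm) {
    r <- as.numeric(ranges[[nm]])
    if (length(r) != 2 || r[1] > r[2]) {
      stop(sprintf("dsa: range for %s must be c(low, high)", nm), call. = FALSE)
    }
    if (base[[nm]] < r[1] - 1e-9 || base[[nm]] > r[2] + 1e-9) {
      stop(sprintf("dsa: range [%g, %g] for %s does not bracket its base value %g",
                   r[1], r[2], nm, base[[nm]]), call. = FALSE)
    }
    if (grepl("^(p_|u_)", nm) && r[2] > 1) {
      stop(sprintf("dsa: range for %s exceeds the unit interval", nm),
           call. = FALSE)
    }
    eval_at <- function(v) {
      theta <- base
      theta[[nm]] <- v
      evaluate_parameter_set(config, theta)[[col]]
    }
    lo <- eval_at(r[1])
    hi <- eval_at(r[2])
    data.frame(name = nm, low_value = r[1], high_value = r[2],
               threshold_low = lo, threshold_high = hi,
               span = abs(hi - lo))
  })
  out <- do.call(rbind, records)
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold_base") <- evaluate_parameter_set(config, base)[[col]]
  attr(out, "perspective") <- perspective
  class(out) <- c("dsa_result", class(out))
  out
}

#' Probabilistic sensitivity analysis
#'
#' Samples all uncertain parameters jointly `n_iter` times from the
#' configured distributions, re-runs the full pipeline per draw, and
#' summarizes the 5th and 95th percentiles of the incremental outcomes and
#' the threshold therapy price under both perspectives. Reproducible:
#' identical seed and configuration give identical output.
#'
#' @param config A loaded configuration.
#' @param n_iter Number of iterations (1000 in the published analysis).
#' @param seed Integer seed for the single generator driving all draws.
#' @param params Optional list of `param_spec` objects; defaults to
#'   [psa_parameters()] of the configuration.
#' @return A `psa_result`: list with `n_iter`, `seed`, `draws` (one row per
#'   iteration: parameters and outcomes) and `summary` (p5 / p95 of each
#'   outcome, plus the count of draws without a finite threshold price).
#' @export
run_psa <- function(config, n_iter = 1000, seed = 1, params = NULL) {
  if (n_iter < 1) stop("`n_iter` must be >= 1", call. = FALSE)
  if (is.null(params)) params <- psa_parameters(config)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  draws <- sample_parameters(params, n_iter)

  outcomes <- do.call(rbind, lapply(seq_len(n_iter), function(i) {
    evaluate_parameter_set(config, draws[i, , drop = FALSE])
  }))

  quantities <- c("delta_medical", "delta_total", "delta_qaly",
                  "threshold_payer", "threshold_payer_ltc")
  summary <- do.call(rbind, lapply(quantities, function(qn) {
    qs <- stats::quantile(outcomes[[qn]], c(0.05, 0.95), names = FALSE)
    data.frame(quantity = qn, p5 = qs[1], p95 = qs[2],
               mean = mean(outcomes[[qn]]))
  }))

  structure(list(n_iter = n_iter, seed = seed,
                 draws = cbind(iteration = seq_len(n_iter), draws, outcomes),
                 summary = summary,
                 n_nonpositive_dqaly = sum(!outcomes$finite_price)),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations, seed %s\n",
              x$n_iter, format(x$seed)))
  if (x$n_nonpositive_dqaly > 0) {
    cat(sprintf("  (%d draw(s) with non-positive incremental QALYs)\n",
                x$n_nonpositive_dqaly))
  }
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-20s 5th-95th percentile: %12.2f  to %12.2f\n",
                s$quantity[i], s$p5[i], s$p95[i]))
  }
  invisible(x)
}
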