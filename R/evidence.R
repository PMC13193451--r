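#' Pooled event proportion
#'
#' Simple pooled proportion of events over totals, used to turn trial-level
#' counts (e.g. 90-day deaths pooled across arms and studies) into a model
#' input probability.
#'
#' @param events Number of patients with the outcome (non-negative integer).
#' @param total Number of patients at risk (positive integer).
#' @return The proportion `events / total` at full precision.
#' @examples
#' pooled_proportion(16, 457) # 90-day death, both arms pooled: 0.035
#' @export
pooled_proportion <- function(events, total) {
  if (!is.numeric(events) || !is.numeric(total)) {
    stop("`events` and `total` must be numeric", call. = FALSE)
  }
  if (any(total <= 0)) {
    stop("`total` must be positive", call. = FALSE)
  }
  if (any(events < 0) || any(events > total)) {
    stop("`events` must lie in [0, total]", call. = FALSE)
  }
  events / total
}

#' Residual disability proportion
#'
#' The proportion with disability (mRS 3-5) is not observed directly; it is
#' the remainder after subtracting the proportions with functional
#' independence (mRS 0-2) and death (mRS 6) from 100%.
#'
#' @param p_functional Proportion with mRS 0-2 at 3 months.
#' @param p_dead Proportion with mRS 6 at 3 months.
#' @return `1 - p_functional - p_dead`.
#' @export
residual_disabled <- function(p_functional, p_dead) {
  check_proportion(p_functional, "p_functional")
  check_proportion(p_dead, "p_dead")
  if (p_functional + p_dead > 1 + 1e-12) {
    stop("`p_functional` + `p_dead` exceeds 1; no residual disability share left",
         call. = FALSE)
  }
  max(0, 1 - p_functional - p_dead)
}

#' Initial state distribution at model entry
#'
#' Builds the month-3 (model entry) distribution over the three aggregated
#' mRS states from the functional-independence and death proportions; the
#' disabled share is the residual (see [residual_disabled()]).
#'
#' @inheritParams residual_disabled
#' @return An `initial_distribution`: a named numeric vector
#'   `(functional, disabled, dead)` summing to 1.
#' @examples
#' build_initial_distribution(0.326, 0.035) # stem cell arm, base case
#' @export
build_initial_distribution <- function(p_functional, p_dead) {
  initial_distribution(p_functional,
                       residual_disabled(p_functional, p_dead),
                       p_dead)
}

#' @rdname build_initial_distribution
#' @param p_disabled Proportion with mRS 3-5.
#' @export
initial_distribution <- function(p_functional, p_disabled, p_dead) {
  x <- c(functional = as.numeric(p_functional),
         disabled = as.numeric(p_disabled),
         dead = as.numeric(p_dead))
  if (any(x < -1e-12) || any(x > 1 + 1e-12)) {
    stop("initial distribution entries must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(x) - 1) > 1e-9) {
    stop(sprintf("initial distribution must sum to 1 (got %.12f)", sum(x)),
         call. = FALSE)
  }
  structure(pmin(pmax(x, 0), 1), class = "initial_distribution")
}

#' Apply a risk ratio to a control-arm proportion
#'
#' Derives the treated-arm proportion with functional independence as
#' `p_control * rr`, clamped at 1. The base-case analysis uses the observed
#' pooled proportions directly; this multiplicative pathway is what the
#' sensitivity analyses vary.
#'
#' @param p_control Control-arm proportion, in `[0, 1]`.
#' @param rr Risk ratio, positive.
#' @return `min(1, p_control * rr)`.
#' @export
apply_risk_ratio <- function(p_control, rr) {
  check_proportion(p_control, "p_control")
  if (!is.numeric(rr) || any(rr <= 0)) {
    stop("`rr` must be positive", call. = FALSE)
  }
  pmin(1, p_control * rr)
}

#' Pairwise risk-ratio meta-analysis
#'
#' Pools two-arm binomial outcome tables into a risk ratio with 95%
#' confidence interval, Cochran's Q and I-squared. The fixed-effect estimate
#' is Mantel-Haenszel with the Greenland-Robins variance; when I-squared
#' exceeds 25% the pooled estimate is refit with DerSimonian-Laird random
#' effects (inverse-variance on the log scale), and the `model` field
#' records which was used. Studies containing any zero cell receive the
#' Haldane-Anscombe continuity correction (0.5 added to all four cells).
#'
#' @param tables A data frame with columns `study_id`, `treated_events`,
#'   `treated_total`, `control_events`, `control_total` (one row per study),
#'   e.g. from [read_trial_table()] or [generate_trials()].
#' @param i2_threshold I-squared percentage above which the random-effects
#'   model is used (strict inequality). Default 25.
#' @return A `meta_result`: list with elements `rr`, `ci_low`, `ci_high`,
#'   `i_squared`, `model` (`"fixed"` or `"random"`), `p_value`, `k`,
#'   `tau2`, `q`.
#' @examples
#' tabs <- data.frame(study_id = "a", treated_events = 30, treated_total = 100,
#'                    control_events = 20, control_total = 100)
#' meta_risk_ratio(tabs)$rr # 1.5
#' @export
meta_risk_ratio <- function(tables, i2_threshold = 25) {
  tables <- validate_trial_table(tables)
  k <- nrow(tables)

  a <- tables$treated_events
  n1 <- tables$treated_total
  c_ <- tables$control_events
  n2 <- tables$control_total

  if (all(a == 0) && all(c_ == 0)) {
    stop("risk ratio undefined: every study has zero events in both arms",
         call. = FALSE)
  }

  # Haldane-Anscombe: correct studies with any zero cell
  zero <- a == 0 | c_ == 0 | a == n1 | c_ == n2
  a <- a + 0.5 * zero
  c_ <- c_ + 0.5 * zero
  n1 <- n1 + 1 * zero
  n2 <- n2 + 1 * zero
  nn <- n1 + n2

  # Mantel-Haenszel pooled RR with Greenland-Robins variance
  r_terms <- a * n2 / nn
  s_terms <- c_ * n1 / nn
  rr_mh <- sum(r_terms) / sum(s_terms)
  p_num <- sum((n1 * n2 * (a + c_) - a * c_ * nn) / nn^2)
  se_mh <- sqrt(p_num / (sum(r_terms) * sum(s_terms)))

  # Per-study log RR and inverse-variance weights for Q / I^2 / DL
  y <- log((a / n1) / (c_ / n2))
  v <- 1 / a - 1 / n1 + 1 / c_ - 1 / n2
  w <- 1 / v
  y_fixed <- sum(w * y) / sum(w)
  q <- sum(w * (y - y_fixed)^2)
  df <- k - 1
  i2 <- if (df == 0 || q <= df) 0 else 100 * (q - df) / q

  if (i2 > i2_threshold) {
    tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
    w_star <- 1 / (v + tau2)
    mu <- sum(w_star * y) / sum(w_star)
    se <- sqrt(1 / sum(w_star))
    est <- exp(mu)
    model <- "random"
  } else {
    tau2 <- 0
    est <- rr_mh
    se <- se_mh
    mu <- log(rr_mh)
    model <- "fixed"
  }

  z <- mu / se
  out <- list(
    rr = est,
    ci_low = exp(mu - stats::qnorm(0.975) * se),
    ci_high = exp(mu + stats::qnorm(0.975) * se),
    i_squared = i2,
    model = model,
    p_value = 2 * stats::pnorm(-abs(z)),
    k = k,
    tau2 = tau2,
    q = q
  )
  structure(out, class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Pooled risk ratio (%s effects, k = %d studies)\n", x$model, x$k))
  cat(sprintf("  RR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$rr, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  I^2 = %.1f%%, Q = %.3f, tau^2 = %.4g\n",
              x$i_squared, x$q, x$tau2))
  invisible(x)
}

#' Read trial outcome tables from CSV
#'
#' @param path Path to a CSV file with columns `study_id`, `treated_events`,
#'   `treated_total`, `control_events`, `control_total`.
#' @return A validated data frame of trial tables.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("trial table file not found: %s", path), call. = FALSE)
  }
  validate_trial_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

validate_trial_table <- function(tables) {
  required <- c("study_id", "treated_events", "treated_total",
                "control_events", "control_total")
  missing <- setdiff(required, names(tables))
  if (length(missing) > 0) {
    stop(sprintf("trial table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(tables) < 1) {
    stop("trial table must contain at least one study", call. = FALSE)
  }
  for (col in c("treated", "control")) {
    ev <- tables[[paste0(col, "_events")]]
    tot <- tables[[paste0(col, "_total")]]
    if (any(tot <= 0)) {
      stop(sprintf("%s arm has a study with total <= 0", col), call. = FALSE)
    }
    if (any(ev < 0) || any(ev > tot)) {
      stop(sprintf("%s arm events must lie in [0, total]", col), call. = FALSE)
    }
  }
  tables
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a proportion in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
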