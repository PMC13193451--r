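#' Economic evaluation settings
#'
#' @param discount_rate Annual discount rate for costs and outcomes
#'   (fraction per year; 0.02 in the base case).
#' @param horizon_months Last model month (120 = 10 years from onset).
#' @param start_month First recorded model month (4).
#' @param fx_jpy_per_usd Exchange rate, JPY per USD (157.2).
#' @param reference_icer_jpy Reference willingness-to-pay, JPY per QALY
#'   (5,000,000, the Japanese health-technology-assessment reference).
#' @return An `econ_settings` object.
#' @export
econ_settings <- function(discount_rate = 0.02, horizon_months = 120,
                          start_month = 4, fx_jpy_per_usd = 157.2,
                          reference_icer_jpy = 5e6) {
  if (discount_rate < 0) stop("`discount_rate` must be >= 0", call. = FALSE)
  if (fx_jpy_per_usd <= 0) stop("`fx_jpy_per_usd` must be positive", call. = FALSE)
  if (reference_icer_jpy <= 0) {
    stop("`reference_icer_jpy` must be positive", call. = FALSE)
  }
  structure(list(discount_rate = discount_rate,
                 horizon_months = horizon_months,
                 start_month = start_month,
                 fx_jpy_per_usd = fx_jpy_per_usd,
                 reference_icer_jpy = reference_icer_jpy),
            class = "econ_settings")
}

#' Monthly discount factor
#'
#' Time zero is stroke onset (month 0); month `m` is discounted by
#' `(1 + rate)^(-m / 12)`.
#'
#' @param rate Annual discount rate (>= 0).
#' @param month Month index (>= 0); vectorized.
#' @return Discount factor(s).
#' @export
discount_factor <- function(rate, month) {
  if (rate < 0) stop("`rate` must be >= 0", call. = FALSE)
  if (any(month < 0)) stop("`month` must be >= 0", call. = FALSE)
  (1 + rate)^(-month / 12)
}

#' Currency conversion
#'
#' @param amount Amount to convert.
#' @param fx Exchange rate in JPY per USD (positive).
#' @return Converted amount.
#' @export
jpy_to_usd <- function(amount, fx) {
  if (any(fx <= 0)) stop("`fx` must be positive", call. = FALSE)
  amount / fx
}

#' @rdname jpy_to_usd
#' @export
usd_to_jpy <- function(amount, fx) {
  if (any(fx <= 0)) stop("`fx` must be positive", call. = FALSE)
  amount * fx
}

#' Incremental cost-effectiveness ratio at a given therapy price
#'
#' `ICER = ((Cost_treated + price) - Cost_control) / (QALY_treated -
#' QALY_control)`, expressed in JPY per QALY. `delta_cost_usd` is the
#' incremental non-therapy cost (treated minus control).
#'
#' @param delta_cost_usd Incremental cost excluding the therapy price (USD).
#' @param sct_price_usd Price of the therapy (USD).
#' @param delta_qaly Incremental QALYs; must be non-zero.
#' @param fx Exchange rate, JPY per USD.
#' @return ICER in JPY per QALY.
#' @export
icer <- function(delta_cost_usd, sct_price_usd, delta_qaly, fx) {
  if (any(fx <= 0)) stop("`fx` must be positive", call. = FALSE)
  if (any(delta_qaly == 0)) {
    sign_txt <- if (all(delta_cost_usd + sct_price_usd <= 0)) "saves money" else "adds cost"
    stop(sprintf(
      "ICER undefined: incremental QALYs are zero (the intervention %s at equal effect)",
      sign_txt), call. = FALSE)
  }
  (delta_cost_usd + sct_price_usd) * fx / delta_qaly
}

#' Threshold therapy price at the reference willingness-to-pay
#'
#' Inverts the ICER equation: the price at which the ICER equals the
#' reference value is
#' `reference_icer_jpy * delta_qaly / fx - delta_cost_usd`.
#'
#' @param delta_cost_usd Incremental non-therapy cost (USD, treated minus
#'   control).
#' @param delta_qaly Incremental QALYs; must be positive for a finite
#'   threshold price.
#' @param settings An [econ_settings()] object.
#' @return Threshold price in USD (full precision; round only for
#'   presentation).
#' @examples
#' threshold_price(-565, 0.10, econ_settings()) # 3745.66 -> $3,746
#' @export
threshold_price <- function(delta_cost_usd, delta_qaly, settings = econ_settings()) {
  if (any(delta_qaly <= 0)) {
    quadrant <- if (all(delta_qaly < 0) && all(delta_cost_usd < 0)) {
      "south-west quadrant: the intervention is cheaper but less effective"
    } else {
      "the intervention is not more effective"
    }
    stop(errorCondition(
      sprintf("no finite threshold price: incremental QALYs <= 0 (%s)", quadrant),
      class = c("sctcea_no_finite_price", "error")))
  }
  threshold_price_value(delta_cost_usd, delta_qaly, settings)
}

# algebraic value without the positivity guard; used by the sensitivity
# machinery, where draws with non-positive incremental QALYs are flagged
# rather than aborted on
threshold_price_value <- function(delta_cost_usd, delta_qaly, settings) {
  settings$reference_icer_jpy * delta_qaly / settings$fx_jpy_per_usd - delta_cost_usd
}

#' Compare two model arms
#'
#' Derives incremental costs and QALYs from two arm results and the
#' threshold therapy price under both payer perspectives: the public health
#' payer (medical costs only) and the public healthcare plus long-term-care
#' payer (medical plus care costs).
#'
#' @param treated,control `arm_result` objects from [accumulate_outcomes()].
#' @param settings An [econ_settings()] object.
#' @return A `cea_result`: list with `delta_medical`, `delta_ltc`,
#'   `delta_total`, `delta_qaly`, and per-perspective threshold prices
#'   `threshold_payer`, `threshold_payer_ltc` (NA with `finite_price =
#'   FALSE` when incremental QALYs are not positive).
#' @export
compare_arms <- function(treated, control, settings = econ_settings()) {
  dq <- treated$qalys - control$qalys
  d_med <- treated$medical_cost - control$medical_cost
  d_ltc <- treated$ltc_cost - control$ltc_cost
  finite <- dq > 0
  structure(list(
    delta_medical = d_med,
    delta_ltc = d_ltc,
    delta_total = d_med + d_ltc,
    delta_qaly = dq,
    finite_price = finite,
    threshold_payer = if (finite) threshold_price_value(d_med, dq, settings) else NA_real_,
    threshold_payer_ltc = if (finite) {
      threshold_price_value(d_med + d_ltc, dq, settings)
    } else NA_real_,
    settings = settings
  ), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Incremental results (treated - control), therapy price excluded\n")
  cat(sprintf("  Medical cost:        $%s\n", format(round(x$delta_medical), big.mark = ",")))
  cat(sprintf("  Long-term care cost: $%s\n", format(round(x$delta_ltc), big.mark = ",")))
  cat(sprintf("  Total cost:          $%s\n", format(round(x$delta_total), big.mark = ",")))
  cat(sprintf("  QALYs:               %.2f\n", x$delta_qaly))
  if (x$finite_price) {
    cat(sprintf("Threshold price at %s JPY/QALY:\n",
                format(x$settings$reference_icer_jpy, big.mark = ",")))
    cat(sprintf("  public health payer:            $%s\n",
                format(round(x$threshold_payer), big.mark = ",")))
    cat(sprintf("  healthcare + long-term care:    $%s\n",
                format(round(x$threshold_payer_ltc), big.mark = ",")))
  } else {
    cat("No finite threshold price: incremental QALYs are not positive\n")
  }
  invisible(x)
}
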