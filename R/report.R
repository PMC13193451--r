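#' Run one scenario of the cost-utility analysis
#'
#' Executes the full deterministic pipeline for one scenario: builds each
#' arm's initial distribution from the configured proportions, runs the
#' Markov cohort with the configured transition matrix, accumulates
#' discounted costs and QALYs, and inverts the ICER equation to the
#' threshold therapy price under both payer perspectives.
#'
#' @param config A configuration from [load_config()] or
#'   [base_case_config()].
#' @param scenario Scenario id; one of the names of `config$scenarios`
#'   (the shipped configuration has `base`, `s1`, `s2`).
#' @return A `run_report`: list with `scenario`, per-arm `treated` /
#'   `control` arm results, the incremental `cea` result, and `provenance`
#'   (config hash, package version).
#' @examples
#' report <- run_scenario(base_case_config(), "base")
#' report$cea$threshold_payer
#' @export
run_scenario <- function(config, scenario = "base") {
  if (!inherits(config, "sctcea_config")) {
    stop("`config` must be a validated configuration (see load_config())",
         call. = FALSE)
  }
  sc <- config$scenarios[[scenario]]
  if (is.null(sc)) {
    stop(sprintf("unknown scenario `%s` (available: %s)", scenario,
                 paste(names(config$scenarios), collapse = ", ")), call. = FALSE)
  }
  settings <- config_settings(config)
  utilities <- utility_set(config$utilities$functional,
                           config$utilities$disabled)
  costs <- config_state_costs(config)

  run_arm <- function(arm) {
    init <- build_initial_distribution(arm$p_functional, arm$p_dead)
    trace <- run_cohort(init, config$transition_matrix,
                        settings$horizon_months, settings$start_month)
    accumulate_outcomes(trace, utilities, costs, settings)
  }
  treated <- run_arm(sc$treated)
  control <- run_arm(sc$control)
  cea <- compare_arms(treated, control, settings)

  structure(list(
    scenario = scenario,
    treated = treated,
    control = control,
    cea = cea,
    provenance = list(
      config_hash = attr(config, "config_hash"),
      config_path = attr(config, "config_path"),
      package_version = as.character(utils::packageVersion("sctcea")))
  ), class = "run_report")
}

# plain-list form used for serialization and round-trip comparison
report_to_list <- function(report) {
  arm <- function(a) {
    list(medical_cost = a$medical_cost, ltc_cost = a$ltc_cost,
         total_cost = a$total_cost, qalys = a$qalys)
  }
  cea <- report$cea
  list(scenario = report$scenario,
       treated = arm(report$treated),
       control = arm(report$control),
       incremental = list(medical_cost = cea$delta_medical,
                          ltc_cost = cea$delta_ltc,
                          total_cost = cea$delta_total,
                          qalys = cea$delta_qaly,
                          finite_price = cea$finite_price,
                          threshold_payer = cea$threshold_payer,
                          threshold_payer_ltc = cea$threshold_payer_ltc),
       provenance = report$provenance)
}

#' Write and read run reports
#'
#' `write_report` serializes a [run_scenario()] report. JSON keeps full
#' precision and round-trips through `read_report`; CSV holds one row per
#' arm plus the incremental row in the published table's column order;
#' the text format is a human-readable table with currency rounded to
#' whole dollars (rounding happens only in this view).
#'
#' @param report A `run_report`.
#' @param path Output file path.
#' @param format `"json"`, `"csv"` or `"text"`; defaults to the extension.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("auto", "json", "csv", "text")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", csv = "csv", "text")
  }
  x <- report_to_list(report)
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (format == "csv") {
    rows <- rbind(
      data.frame(row = "treated", as.data.frame(x$treated)),
      data.frame(row = "control", as.data.frame(x$control)),
      data.frame(row = "incremental", as.data.frame(x$incremental[
        c("medical_cost", "ltc_cost", "total_cost", "qalys")])))
    rows$threshold_payer <- c(NA, NA, x$incremental$threshold_payer)
    rows$threshold_payer_ltc <- c(NA, NA, x$incremental$threshold_payer_ltc)
    rows <- cbind(scenario = x$scenario, rows)
    utils::write.csv(rows, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(utils::capture.output(print(report)), con)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' @export
print.run_report <- function(x, ...) {
  l <- report_to_list(x)
  fmt_usd <- function(v) format(round(v), big.mark = ",", trim = TRUE)
  cat(sprintf("Scenario: %s\n", x$scenario))
  cat(sprintf("%-12s %14s %20s %14s %12s\n", "",
              "Medical ($US)", "Long-term care ($US)", "Total ($US)", "QALYs"))
  for (nm in c("treated", "control")) {
    a <- l[[nm]]
    cat(sprintf("%-12s %14s %20s %14s %12.2f\n", nm,
                fmt_usd(a$medical_cost), fmt_usd(a$ltc_cost),
                fmt_usd(a$total_cost), a$qalys))
  }
  inc <- l$incremental
  cat(sprintf("%-12s %14s %20s %14s %12.2f\n", "incremental",
              fmt_usd(inc$medical_cost), fmt_usd(inc$ltc_cost),
              fmt_usd(inc$total_cost), inc$qalys))
  if (isTRUE(inc$finite_price)) {
    cat(sprintf("Threshold therapy price: $%s (payer), $%s (payer + long-term care)\n",
                fmt_usd(inc$threshold_payer), fmt_usd(inc$threshold_payer_ltc)))
  } else {
    cat("No finite threshold price: incremental QALYs are not positive\n")
  }
  invisible(x)
}
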