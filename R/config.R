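#' Load and validate a model configuration
#'
#' Reads a YAML (or JSON) configuration holding every model input: the
#' per-scenario initial mRS-state proportions, the monthly transition
#' matrix, utilities, per-state hospitalization costs, per-mRS medical
#' costs with mixing weights, the long-term-care tier costs and mapping,
#' economic settings, and the sensitivity-analysis ranges and
#' distributions. Every parameter is validated against its domain; a
#' missing `discount_rate` defaults to 0.02 with a warning.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `sctcea_config` list. The MD5 hash of the file and
#'   its path are attached as attributes `config_hash` and `config_path`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  config <- validate_config(raw)
  attr(config, "config_hash") <- unname(tools::md5sum(path))
  attr(config, "config_path") <- path
  config
}

#' @rdname load_config
#' @param config A raw configuration list (as parsed from YAML/JSON).
#' @export
validate_config <- function(config) {
  need <- function(key) {
    if (is.null(config[[key]])) {
      stop(sprintf("configuration lacks required key `%s`", key), call. = FALSE)
    }
    config[[key]]
  }
  fail_at <- function(key, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("%s: %s", key, conditionMessage(e)), call. = FALSE)
    })
  }

  eco <- need("economics")
  if (is.null(eco$discount_rate)) {
    warning("configuration omits `economics.discount_rate`; default 0.02 applied",
            call. = FALSE)
    eco$discount_rate <- 0.02
  }
  if (is.null(eco$horizon_months)) eco$horizon_months <- 120
  if (is.null(eco$start_month)) eco$start_month <- 4
  fail_at("economics", econ_settings(eco$discount_rate, eco$horizon_months,
                                     eco$start_month, eco$fx_jpy_per_usd,
                                     eco$reference_icer_jpy))
  config$economics <- eco

  config$transition_matrix <- fail_at("transition_matrix",
                                      transition_matrix(need("transition_matrix")))

  scenarios <- need("scenarios")
  for (nm in names(scenarios)) {
    for (arm in c("treated", "control")) {
      a <- scenarios[[nm]][[arm]]
      if (is.null(a)) {
        stop(sprintf("scenarios.%s: missing `%s` arm", nm, arm), call. = FALSE)
      }
      fail_at(sprintf("scenarios.%s.%s", nm, arm),
              build_initial_distribution(a$p_functional, a$p_dead))
    }
  }

  ut <- need("utilities")
  fail_at("utilities", utility_set(ut$functional, ut$disabled,
                                   if (is.null(ut$dead)) 0 else ut$dead))

  hosp <- unlist(need("hospitalization_by_state"))
  if (length(hosp) != 3 || any(hosp < 0)) {
    stop("hospitalization_by_state: must be 3 non-negative costs", call. = FALSE)
  }
  config$hospitalization_by_state <- as.numeric(hosp)

  if (!is.null(config$medical_cost_by_mrs)) {
    mc <- unlist(config$medical_cost_by_mrs)
    if (length(mc) != 7 || any(mc < 0)) {
      stop("medical_cost_by_mrs: must be 7 non-negative costs (mRS 0-6)",
           call. = FALSE)
    }
    config$medical_cost_by_mrs <- as.numeric(mc)
  }

  fail_at("ltc_levels / ltc_mapping / mix_weights",
          ltc_schedule(need("ltc_levels"), need("ltc_mapping"),
                       need("mix_weights")))

  eff <- need("efficacy")
  fail_at("efficacy", {
    check_proportion(eff$p_control_functional, "p_control_functional")
    check_proportion(eff$p_dead, "p_dead")
    apply_risk_ratio(eff$p_control_functional, eff$risk_ratio)
  })

  structure(config, class = "sctcea_config")
}

# settings object from the economics section of a validated config
config_settings <- function(config) {
  eco <- config$economics
  econ_settings(eco$discount_rate, eco$horizon_months, eco$start_month,
                eco$fx_jpy_per_usd, eco$reference_icer_jpy)
}

# per-state cost set implied by a validated config
config_state_costs <- function(config) {
  schedule <- ltc_schedule(config$ltc_levels, config$ltc_mapping,
                           config$mix_weights)
  state_costs(
    hospitalization = config$hospitalization_by_state,
    ltc_monthly = c(ltc_monthly_cost("functional", schedule),
                    ltc_monthly_cost("disabled", schedule), 0))
}
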