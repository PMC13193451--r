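# Synthetic-data generators: trial tables with a known true risk ratio and
# random valid transition matrices, so the meta-analytic and Markov stages
# can be exercised and calibrated without any external data.

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate synthetic two-arm trial tables
#'
#' Draws per-study binomial outcome counts with control-arm event
#' probability `base_risk` and treated-arm probability `base_risk * RR_i`,
#' where each study's log risk ratio is normal with mean `log(true_rr)` and
#' standard deviation `between_study_sd` (0 gives homogeneous studies, the
#' case matching the published efficacy dataset, whose I-squared was 0%).
#'
#' @param n_studies Number of studies.
#' @param n_per_arm Patients per arm (scalar or length `n_studies`).
#' @param base_risk Control-arm event probability, in (0, 1).
#' @param true_rr True risk ratio (positive).
#' @param between_study_sd SD of the study-level log risk ratio (>= 0).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return A trial-table data frame (see [meta_risk_ratio()]). If any
#'   study's treated-arm risk had to be clamped at 1, the table carries the
#'   attribute `clamped` with the affected study indices and a warning is
#'   issued.
#' @export
generate_trials <- function(n_studies, n_per_arm, base_risk, true_rr,
                            between_study_sd = 0, seed = 1) {
  if (base_risk <= 0 || base_risk >= 1) {
    stop("`base_risk` must lie in (0, 1)", call. = FALSE)
  }
  if (true_rr <= 0) stop("`true_rr` must be positive", call. = FALSE)
  if (between_study_sd < 0) stop("`between_study_sd` must be >= 0", call. = FALSE)
  if (any(n_per_arm < 1)) stop("`n_per_arm` must be >= 1", call. = FALSE)
  n_per_arm <- rep_len(n_per_arm, n_studies)

  with_seed(seed, {
    rr_i <- exp(stats::rnorm(n_studies, log(true_rr), between_study_sd))
    p_treat <- base_risk * rr_i
    clamped <- which(p_treat > 1)
    p_treat <- pmin(1, p_treat)
    tab <- data.frame(
      study_id = sprintf("study_%02d", seq_len(n_studies)),
      treated_events = stats::rbinom(n_studies, n_per_arm, p_treat),
      treated_total = n_per_arm,
      control_events = stats::rbinom(n_studies, n_per_arm, base_risk),
      control_total = n_per_arm)
    if (length(clamped) > 0) {
      warning(sprintf("treated-arm risk clamped at 1 for %d study(ies)",
                      length(clamped)), call. = FALSE)
      attr(tab, "clamped") <- clamped
    }
    tab
  })
}

#' Generate a random valid transition matrix
#'
#' Draws the four free monthly probabilities uniformly from the given
#' ranges and assembles a matrix with an absorbing death state; rows are
#' renormalized if the drawn exits from a state exceed 1, so the result
#' always passes [validate_transition_matrix()].
#'
#' @param seed Integer seed.
#' @param death_range Bounds for the monthly death probabilities (from
#'   either living state).
#' @param improvement_range Bounds for disabled-to-functional recovery.
#' @param deterioration_range Bounds for functional-to-disabled decline.
#' @return A [transition_matrix()].
#' @export
generate_transition_matrix <- function(seed = 1,
                                       death_range = c(0, 0.05),
                                       improvement_range = c(0, 0.05),
                                       deterioration_range = c(0, 0.05)) {
  check_range01 <- function(r, nm) {
    if (length(r) != 2 || any(r < 0) || any(r > 1) || r[1] > r[2]) {
      stop(sprintf("`%s` must be an increasing pair within [0, 1]", nm),
           call. = FALSE)
    }
  }
  check_range01(death_range, "death_range")
  check_range01(improvement_range, "improvement_range")
  check_range01(deterioration_range, "deterioration_range")

  with_seed(seed, {
    f_dis <- stats::runif(1, deterioration_range[1], deterioration_range[2])
    f_dead <- stats::runif(1, death_range[1], death_range[2])
    dis_f <- stats::runif(1, improvement_range[1], improvement_range[2])
    dis_dead <- stats::runif(1, death_range[1], death_range[2])
    if (f_dis + f_dead > 1) {
      s <- f_dis + f_dead; f_dis <- f_dis / s; f_dead <- f_dead / s
    }
    if (dis_f + dis_dead > 1) {
      s <- dis_f + dis_dead; dis_f <- dis_f / s; dis_dead <- dis_dead / s
    }
    transition_matrix(rbind(c(1 - f_dis - f_dead, f_dis, f_dead),
                            c(dis_f, 1 - dis_f - dis_dead, dis_dead),
                            c(0, 0, 1)))
  })
}

#' The shipped base-case configuration
#'
#' Loads the packaged configuration carrying the published base-case and
#' scenario parameters (initial mRS distributions, utilities, costs,
#' discounting, sensitivity ranges and distributions) together with the
#' package's calibrated stand-in transition matrix; see the packaged YAML
#' file's `known_issues` field and the methods vignette for which inputs
#' are published values and which are synthetic stand-ins.
#'
#' @return A validated configuration (see [load_config()]).
#' @examples
#' cfg <- base_case_config()
#' cfg$scenarios$base$treated
#' @export
base_case_config <- function() {
  load_config(system.file("extdata", "base_case.yaml", package = "sctcea",
                          mustWork = TRUE))
}
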