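markov_states <- c("functional", "disabled", "dead")

#' Monthly transition matrix
#'
#' Constructs and validates the 3x3 monthly transition matrix over the
#' states functional independence (mRS 0-2), disability (mRS 3-5) and death
#' (mRS 6). Death is absorbing.
#'
#' @param x A 3x3 numeric matrix or nested list (rows = from-state,
#'   columns = to-state, ordered functional / disabled / dead).
#' @return A validated `transition_matrix`.
#' @export
transition_matrix <- function(x) {
  if (is.list(x)) x <- do.call(rbind, lapply(x, unlist))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  dimnames(x) <- list(markov_states, markov_states)
  validate_transition_matrix(structure(x, class = c("transition_matrix", "matrix")))
}

#' @rdname transition_matrix
#' @param m Object to validate.
#' @export
validate_transition_matrix <- function(m) {
  if (!is.matrix(m) || !all(dim(m) == c(3, 3)) || !is.numeric(m)) {
    stop("transition matrix must be a 3x3 numeric matrix", call. = FALSE)
  }
  if (any(m < 0) || any(m > 1)) {
    bad <- which(m < 0 | m > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("transition matrix: entry [%d, %d] outside [0, 1]",
                 bad[1], bad[2]), call. = FALSE)
  }
  sums <- rowSums(m)
  off <- which(abs(sums - 1) > 1e-9)
  if (length(off) > 0) {
    stop(sprintf("transition matrix: row %d (%s) sums to %.12f, not 1",
                 off[1], markov_states[off[1]], sums[off[1]]), call. = FALSE)
  }
  if (any(abs(m[3, ] - c(0, 0, 1)) > 1e-12)) {
    stop("transition matrix: death must be absorbing (dead row must be 0, 0, 1)",
         call. = FALSE)
  }
  if (!inherits(m, "transition_matrix")) {
    m <- structure(m, class = c("transition_matrix", class(m)))
  }
  m
}

#' Run the Markov cohort
#'
#' Propagates the cohort's state occupancy month by month from model entry
#' (month 4, i.e. 3 months after stroke onset) to the end of the horizon.
#' Occupancy at the first recorded month equals the initial distribution;
#' each subsequent month is the previous row right-multiplied by the
#' transition matrix.
#'
#' @param init An [initial_distribution()].
#' @param m A [transition_matrix()].
#' @param horizon_months Last recorded month (default 120, a 10-year
#'   horizon counted from stroke onset).
#' @param start_month First recorded month (default 4).
#' @return A `cohort_trace`: numeric matrix with one row per month
#'   (rownames are the month indices) and columns
#'   `functional`, `disabled`, `dead`.
#' @export
run_cohort <- function(init, m, horizon_months = 120, start_month = 4) {
  if (!inherits(init, "initial_distribution")) {
    init <- initial_distribution(init[1], init[2], init[3])
  }
  m <- validate_transition_matrix(m)
  if (horizon_months < start_month) {
    stop("`horizon_months` must be >= `start_month`", call. = FALSE)
  }
  months <- seq(start_month, horizon_months)
  trace <- matrix(NA_real_, nrow = length(months), ncol = 3,
                  dimnames = list(months, markov_states))
  occ <- as.numeric(init)
  for (i in seq_along(months)) {
    trace[i, ] <- occ
    occ <- as.numeric(occ %*% m)
  }
  structure(trace, months = months, class = c("cohort_trace", "matrix"))
}

#' Utility weights per state
#'
#' @param functional Utility of functional independence (default 0.71).
#' @param disabled Utility of disability (default 0.31).
#' @param dead Utility of death; must be 0.
#' @return A `utility_set`: named numeric vector of QALY weights per year.
#' @export
utility_set <- function(functional = 0.71, disabled = 0.31, dead = 0) {
  u <- c(functional = functional, disabled = disabled, dead = dead)
  if (u[["dead"]] != 0) stop("utility of death must be 0", call. = FALSE)
  if (any(u < 0) || any(u > 1)) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  structure(u, class = "utility_set")
}

#' Accumulate discounted costs and QALYs over the cohort trace
#'
#' QALYs and long-term-care costs accrue monthly over the recorded months
#' (utility / 12 and USD per month respectively, each weighted by state
#' occupancy and the monthly discount factor). The index hospitalization
#' cost is charged once at model entry, attributed by initial state and
#' undiscounted, since it precedes the model start.
#'
#' @param trace A [run_cohort()] trace.
#' @param utilities A [utility_set()].
#' @param costs A [state_costs()] object.
#' @param settings An [econ_settings()] object; its horizon must match the
#'   trace.
#' @return An `arm_result`: list with discounted `medical_cost`, `ltc_cost`,
#'   `total_cost` (USD) and `qalys`.
#' @export
accumulate_outcomes <- function(trace, utilities, costs, settings) {
  if (!inherits(trace, "cohort_trace")) {
    stop("`trace` must be a cohort_trace from run_cohort()", call. = FALSE)
  }
  months <- attr(trace, "months")
  if (min(months) != settings$start_month ||
      max(months) != settings$horizon_months) {
    stop(sprintf(
      "horizon mismatch: trace covers months %d-%d but settings specify %d-%d",
      min(months), max(months), settings$start_month, settings$horizon_months),
      call. = FALSE)
  }
  df <- discount_factor(settings$discount_rate, months)

  occ_w <- trace * df  # rows weighted by the monthly discount factor
  qalys <- sum(occ_w %*% (as.numeric(utilities) / 12))
  ltc <- sum(occ_w %*% costs$ltc_monthly)
  medical <- sum(trace[1, ] * costs$hospitalization)

  structure(list(medical_cost = medical, ltc_cost = ltc,
                 total_cost = medical + ltc, qalys = qalys),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("Medical cost:        $%s\n", format(round(x$medical_cost), big.mark = ",")))
  cat(sprintf("Long-term care cost: $%s\n", format(round(x$ltc_cost), big.mark = ",")))
  cat(sprintf("Total cost:          $%s\n", format(round(x$total_cost), big.mark = ",")))
  cat(sprintf("QALYs:               %.2f\n", x$qalys))
  invisible(x)
}
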