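#' Consumer-price-index adjustment
#'
#' Inflates (or deflates) a cost from the price level of one year to
#' another, e.g. hospitalization costs surveyed in 2015 brought to 2023
#' prices by multiplying by 104.7 / 97.8.
#'
#' @param cost Cost in currency units.
#' @param index_new CPI of the target year.
#' @param index_old CPI of the year the cost was observed in (positive).
#' @return `cost * index_new / index_old`.
#' @export
cpi_adjust <- function(cost, index_new, index_old) {
  if (!is.numeric(index_old) || any(index_old <= 0)) {
    stop("`index_old` must be positive", call. = FALSE)
  }
  cost * index_new / index_old
}

#' Weighted per-state cost aggregation
#'
#' Collapses per-mRS costs onto an aggregated health state as the weighted
#' arithmetic mean, with weights taken from an observed mRS distribution
#' (e.g. 47:46:61 for mRS 0:1:2 and 66:65:45 for mRS 3:4:5).
#'
#' @param costs Numeric vector of per-mRS costs.
#' @param weights Numeric vector of non-negative weights, same length,
#'   positive sum.
#' @return The weighted mean cost.
#' @examples
#' aggregate_state_cost(c(5866, 7899, 11236), c(47, 46, 61))
#' @export
aggregate_state_cost <- function(costs, weights) {
  if (length(costs) != length(weights)) {
    stop("`costs` and `weights` must have the same length", call. = FALSE)
  }
  if (any(costs < 0)) stop("`costs` must be non-negative", call. = FALSE)
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("`weights` must be non-negative with positive sum", call. = FALSE)
  }
  sum(costs * weights) / sum(weights)
}

#' Long-term-care cost schedule
#'
#' Bundles the monthly cost of each nursing-care insurance tier (support
#' levels 1-2, care levels 1-5), the per-mRS mapping onto those tiers, and
#' the mRS mixing weights inside each aggregated state. Long-term care is
#' free of charge in the model for mRS 0 (complete independence) and mRS 6
#' (death), so those scores need no mapping entry.
#'
#' @param levels Named numeric vector of monthly costs (USD/month) per care
#'   tier, e.g. `c(support_1 = 142, ..., care_5 = 1936)`.
#' @param mapping Named list with entries `mrs_1` .. `mrs_5`. Each entry is
#'   a list with `users` (proportion of patients at that mRS score using
#'   care services, in `[0, 1]`) and `levels` (named proportions over care
#'   tiers, summing to at most 1).
#' @param mix_weights List with `functional` (weights for mRS 0:1:2) and
#'   `disabled` (weights for mRS 3:4:5).
#' @return An `ltc_schedule` object.
#' @export
ltc_schedule <- function(levels, mapping, mix_weights) {
  levels <- unlist(levels)
  if (any(levels < 0)) stop("care-tier costs must be non-negative", call. = FALSE)
  for (nm in names(mapping)) {
    entry <- mapping[[nm]]
    if (is.null(entry$users) || entry$users < 0 || entry$users > 1) {
      stop(sprintf("ltc mapping for %s: `users` must be a proportion in [0, 1]", nm),
           call. = FALSE)
    }
    props <- unlist(entry$levels)
    if (any(props < 0) || any(props > 1)) {
      stop(sprintf("ltc mapping for %s: tier proportions must lie in [0, 1]", nm),
           call. = FALSE)
    }
    unknown <- setdiff(names(props), names(levels))
    if (length(unknown) > 0) {
      stop(sprintf("ltc mapping for %s refers to unknown tier(s): %s",
                   nm, paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  for (side in c("functional", "disabled")) {
    w <- unlist(mix_weights[[side]])
    if (length(w) != 3 || any(w < 0) || sum(w) <= 0) {
      stop(sprintf("`mix_weights$%s` must be 3 non-negative weights with positive sum",
                   side), call. = FALSE)
    }
  }
  structure(list(levels = levels, mapping = mapping,
                 mix_weights = lapply(mix_weights, unlist)),
            class = "ltc_schedule")
}

# expected monthly LTC cost for one mRS score under the schedule
mrs_monthly_ltc <- function(mrs, schedule) {
  if (mrs %in% c(0, 6)) return(0)
  key <- paste0("mrs_", mrs)
  entry <- schedule$mapping[[key]]
  if (is.null(entry)) {
    stop(sprintf("ltc schedule has no mapping for %s", key), call. = FALSE)
  }
  props <- unlist(entry$levels)
  entry$users * sum(props * schedule$levels[names(props)])
}

#' Expected monthly long-term-care cost of an aggregated state
#'
#' Averages the per-mRS expected monthly care cost (care-service user
#' proportion times the tier mix times tier costs) over the mRS scores that
#' make up the state, using the schedule's mixing weights. Death carries no
#' care cost.
#'
#' @param state One of `"functional"`, `"disabled"`, `"dead"`.
#' @param schedule An [ltc_schedule()].
#' @return Expected USD per month for a patient occupying `state`.
#' @export
ltc_monthly_cost <- function(state, schedule) {
  state <- match.arg(state, c("functional", "disabled", "dead"))
  if (!inherits(schedule, "ltc_schedule")) {
    stop("`schedule` must be an ltc_schedule", call. = FALSE)
  }
  if (state == "dead") return(0)
  scores <- if (state == "functional") 0:2 else 3:5
  w <- schedule$mix_weights[[state]]
  costs <- vapply(scores, mrs_monthly_ltc, numeric(1), schedule = schedule)
  sum(costs * w) / sum(w)
}

#' Per-state cost set
#'
#' Holds the one-off hospitalization cost charged at model entry and the
#' recurring monthly long-term-care cost for each aggregated state.
#'
#' @param hospitalization Named or unnamed numeric length-3 vector of index
#'   hospitalization costs (USD) for functional / disabled / dead.
#' @param ltc_monthly Numeric length-3 vector of monthly care costs
#'   (USD/month); the dead entry must be 0.
#' @return A `state_costs` object.
#' @export
state_costs <- function(hospitalization, ltc_monthly) {
  states <- c("functional", "disabled", "dead")
  hospitalization <- stats::setNames(as.numeric(hospitalization), states)
  ltc_monthly <- stats::setNames(as.numeric(ltc_monthly), states)
  if (any(hospitalization < 0) || any(ltc_monthly < 0)) {
    stop("state costs must be non-negative", call. = FALSE)
  }
  if (ltc_monthly[["dead"]] != 0) {
    stop("monthly long-term-care cost must be 0 for the dead state", call. = FALSE)
  }
  structure(list(hospitalization = hospitalization, ltc_monthly = ltc_monthly),
            class = "state_costs")
}
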