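# Weekly-cycle Markov cohort engine: 26-week expected per-patient cost and
# effectiveness per arm, in closed form and by microsimulation. Each cycle a
# patient can independently incur an ED visit and/or an unplanned
# hospitalization and returns to Well (no mortality over the 6-month
# horizon).

#' Model configuration
#'
#' @param horizon Cycles (weeks) in the horizon; default 26 (6 months).
#' @param cohort_size Patients in the simulated cohort; default 10,000.
#' @param include_development Include the per-patient development share in
#'   intervention costs? Default `TRUE`.
#' @param visit_multiplier Scale weekly event costs by the conditional
#'   visit multiplicity (visits per event-week)? Default `TRUE`; with
#'   `FALSE` each event-week accrues a single visit/stay.
#' @param psa_outer Second-order (parameter) draws in the PSA; default 1000.
#' @param psa_inner Patients per draw when the PSA inner loop is a
#'   microsimulation; default 1000.
#' @param psa_inner_microsim Use the microsimulation inner loop instead of
#'   the closed form? Default `FALSE`.
#' @param wtp_grid Willingness-to-pay thresholds, dollars per 1-point
#'   burden reduction; default 0 to 20,000 by 250.
#' @param seed Integer seed for all stochastic stages; no default.
#' @return A validated list of class `model_config`.
#' @export
model_config <- function(horizon = 26, cohort_size = 10000,
                         include_development = TRUE, visit_multiplier = TRUE,
                         psa_outer = 1000, psa_inner = 1000,
                         psa_inner_microsim = FALSE,
                         wtp_grid = seq(0, 20000, by = 250),
                         seed = NULL) {
  chk <- function(ok, msg) if (!ok) stop("model_config: ", msg, call. = FALSE)
  chk(horizon >= 1, "horizon must be >= 1 week")
  chk(cohort_size >= 1, "cohort_size must be >= 1")
  chk(psa_outer >= 1 && psa_inner >= 1, "psa_outer and psa_inner must be >= 1")
  chk(all(wtp_grid >= 0), "wtp_grid values must be >= 0")
  chk(is.logical(include_development) && is.logical(visit_multiplier),
      "flags must be logical")
  structure(list(horizon = as.integer(horizon),
                 cohort_size = as.integer(cohort_size),
                 include_development = include_development,
                 visit_multiplier = visit_multiplier,
                 psa_outer = as.integer(psa_outer),
                 psa_inner = as.integer(psa_inner),
                 psa_inner_microsim = psa_inner_microsim,
                 wtp_grid = as.numeric(wtp_grid),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "model_config")
}

#' Expected unplanned-care cost per model cycle
#'
#' With the visit multiplier on (the default), a cycle accrues
#' `p_ed * n_ed * c_ed + p_hosp * n_hosp * c_night * los`; with it off, the
#' single-visit form `p_ed * c_ed + p_hosp * c_night * los`.
#'
#' @param u Utilization parameters (one-row `data.frame` or list with
#'   `p_ed`, `n_ed`, `p_hosp`, `n_hosp`, `los`).
#' @param costs A `cost_inputs` list.
#' @param visit_multiplier Apply conditional visit multiplicities?
#' @return Expected cost in dollars per patient-week.
#' @export
expected_weekly_cost <- function(u, costs = default_costs(),
                                 visit_multiplier = TRUE) {
  u <- as.list(u)
  m_ed <- if (visit_multiplier) u$n_ed else 1
  m_hosp <- if (visit_multiplier) u$n_hosp else 1
  u$p_ed * m_ed * costs$c_ed_visit +
    u$p_hosp * m_hosp * costs$c_night * u$los
}

#' Deterministic (closed-form) strategy outcome
#'
#' Expected 26-week per-patient total cost — horizon times the expected
#' weekly unplanned-care cost, plus the arm's intervention cost — with the
#' calibrated horizon-mean burden score passed through as effectiveness.
#'
#' @param u One-row utilization `data.frame` (with an `arm` column) or list.
#' @param costs A `cost_inputs` list.
#' @param effect_score Calibrated horizon-mean burden score of the arm.
#' @param config A [model_config()].
#' @return One-row `data.frame`: `arm`, `cost`, `effect`, `se` (0).
#' @export
run_deterministic <- function(u, costs = default_costs(), effect_score,
                              config = model_config()) {
  u <- as.list(u)
  if (missing(effect_score) || is.null(effect_score) || is.na(effect_score)) {
    stop("effect_score (calibrated burden trajectory mean) is required",
         call. = FALSE)
  }
  total <- config$horizon *
    expected_weekly_cost(u, costs, config$visit_multiplier) +
    intervention_cost(u$arm, costs, config$include_development)
  data.frame(arm = u$arm, cost = total, effect = effect_score, se = 0,
             stringsAsFactors = FALSE)
}

#' Microsimulated strategy outcome
#'
#' Simulates `config$cohort_size` patients through the weekly cycle tree:
#' each week a patient independently incurs any-ED-visit and
#' any-hospitalization events with the arm's weekly probabilities; an
#' event-week accrues a visit count of 1 + Poisson(n - 1) and, per
#' hospitalization, a gamma length of stay, all costed at the unit prices.
#'
#' @inheritParams run_deterministic
#' @param seed Integer seed (required).
#' @return One-row `data.frame`: `arm`, `cost` (cohort mean), `effect`,
#'   `se` (Monte Carlo standard error of the mean).
#' @export
run_cohort_simulation <- function(u, costs = default_costs(), effect_score,
                                  config = model_config(), seed) {
  if (missing(seed) || is.null(seed)) {
    stop("run_cohort_simulation() requires an explicit seed", call. = FALSE)
  }
  u <- as.list(u)
  N <- config$cohort_size
  T <- config$horizon
  withr::with_seed(as.integer(seed), {
    ed_weeks <- stats::rbinom(N, T, u$p_ed)
    hosp_weeks <- stats::rbinom(N, T, u$p_hosp)
    if (config$visit_multiplier) {
      # sum of k iid 1 + Pois(n-1) counts is k + Pois(k*(n-1))
      visits <- ed_weeks + stats::rpois(N, ed_weeks * (u$n_ed - 1))
      stays <- hosp_weeks + stats::rpois(N, hosp_weeks * (u$n_hosp - 1))
    } else {
      visits <- ed_weeks
      stays <- hosp_weeks
    }
    if (u$los_sd > 0) {
      # sum of k iid gamma(shape, scale) stays is gamma(k*shape, scale)
      shape <- (u$los / u$los_sd)^2
      los_tot <- numeric(N)
      pos <- stays > 0
      los_tot[pos] <- stats::rgamma(sum(pos), shape = stays[pos] * shape,
                                    scale = u$los_sd^2 / u$los)
    } else {
      los_tot <- stays * u$los
    }
    cost <- intervention_cost(u$arm, costs, config$include_development) +
      visits * costs$c_ed_visit + los_tot * costs$c_night
    data.frame(arm = u$arm, cost = mean(cost), effect = effect_score,
               se = stats::sd(cost) / sqrt(N), stringsAsFactors = FALSE)
  })
}

#' Base-case outcomes for every arm
#'
#' Runs the deterministic engine for each arm, pairing Table-style
#' utilization inputs with calibrated effectiveness scores.
#'
#' @param utilization `data.frame` of utilization parameters, one row per
#'   arm (see [default_utilization()]).
#' @param costs A `cost_inputs` list.
#' @param effects Named numeric vector of horizon-mean burden scores by
#'   arm, or a `data.frame` with `arm` and `effect_score` columns (e.g.
#'   [default_burden_curves()]).
#' @param config A [model_config()].
#' @return `data.frame` of strategy outcomes, one row per arm.
#' @export
#' @examples
#' base_case()
base_case <- function(utilization = default_utilization(),
                      costs = default_costs(),
                      effects = default_burden_curves(),
                      config = model_config()) {
  if (is.data.frame(effects)) {
    effects <- stats::setNames(effects$effect_score, effects$arm)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(utilization)), function(i) {
    arm <- utilization$arm[i]
    run_deterministic(utilization[i, ], costs, effects[[arm]], config)
  }))
  rownames(out) <- NULL
  out
}
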