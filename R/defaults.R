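#' Trial arm identifiers
#'
#' The five intervention arms of the SCH component-evaluation trial:
#' automated self-management coaching alone (`SCC`), coaching plus a visible
#' activity tracker (`SCC_AT`), nurse-practitioner follow-up (`NP`), NP
#' follow-up with guideline-based decision support (`NP_DSS`), and the
#' complete SCH intervention combining coaching, tracker and NP follow-up
#' with decision support (`COMPLETE_SCH`).
#'
#' @return Character vector of the five arm identifiers, in a fixed order.
#' @export
#' @examples
#' sch_arms()
sch_arms <- function() {
  c("SCC", "SCC_AT", "NP", "NP_DSS", "COMPLETE_SCH")
}

assert_arm <- function(arm) {
  if (length(arm) != 1L || !arm %in% sch_arms()) {
    stop("unknown arm '", paste(arm, collapse = ","),
         "'; must be one of ", paste(sch_arms(), collapse = ", "),
         call. = FALSE)
  }
  arm
}

#' Default weekly utilization parameters
#'
#' Per-arm weekly event probabilities, conditional visit multiplicities and
#' hospital length of stay (mean and SD), as estimated from the trial's
#' medical-record follow-up. Probabilities are fractions per week;
#' conditional counts are visits per event-week; LOS is nights per
#' hospitalization.
#'
#' @return A `data.frame` with one row per arm and columns `arm`,
#'   `n_patients`, `p_ed`, `p_ed_sd`, `n_ed`, `n_ed_sd`, `p_hosp`,
#'   `p_hosp_sd`, `n_hosp`, `n_hosp_sd`, `los`, `los_sd`.
#' @export
default_utilization <- function() {
  data.frame(
    arm        = sch_arms(),
    n_patients = c(143L, 147L, 150L, 157L, 171L),
    p_ed       = c(0.037, 0.042, 0.044, 0.031, 0.047),
    p_ed_sd    = c(0.079, 0.108, 0.098, 0.066, 0.144),
    n_ed       = c(1.6, 2.0, 1.7, 2.1, 1.7),
    n_ed_sd    = c(0.8, 1.8, 1.0, 2.9, 1.8),
    p_hosp     = c(0.034, 0.025, 0.030, 0.020, 0.027),
    p_hosp_sd  = c(0.089, 0.069, 0.094, 0.053, 0.085),
    n_hosp     = c(1.3, 1.3, 1.4, 1.7, 1.3),
    n_hosp_sd  = c(0.4, 0.7, 0.6, 1.9, 0.6),
    los        = c(4.7, 5.0, 5.2, 3.6, 4.7),
    los_sd     = c(4.2, 4.6, 3.4, 2.2, 4.4),
    stringsAsFactors = FALSE
  )
}

#' Default cost inputs (2023 USD)
#'
#' Unit costs of unplanned care, system development cost and its default
#' per-patient share, NP labor inputs, and the per-patient intervention cost
#' of each arm. The per-patient development share defaults to $1253 — the
#' uniform difference between the with- and without-development cost
#' variants; the $491,118 development total is carried as metadata.
#'
#' @return A list of class `cost_inputs`.
#' @export
default_costs <- function() {
  structure(list(
    c_ed_visit      = 1135, c_ed_visit_sd = 33,
    c_night         = 3574, c_night_sd    = 122,
    dev_total       = 491118,
    dev_per_patient = 1253,
    np_wage         = 59.80,
    np_hours_dss    = 19.79,
    np_hours_nondss = 11.46,
    intervention_cost_per_patient = c(
      SCC = 1253, SCC_AT = 1253, NP = 1309, NP_DSS = 1343, COMPLETE_SCH = 1340
    )
  ), class = "cost_inputs")
}

#' Default symptom-burden curves
#'
#' Quadratic weekly burden curves S(t) = a + b*t + c*t^2 (t in weeks,
#' 0-10 scale, lower is better) used as the generating curves of the
#' synthetic cohort and as the calibrated effectiveness input of the base
#' case. The shared shape (slight early rise peaking near week 10, then
#' decline) reflects symptom accrual over early chemotherapy cycles; the
#' intercepts are set so each arm's 26-week horizon mean equals its
#' estimated 6-month symptom-burden score.
#'
#' @return A `data.frame` with columns `arm`, `a`, `b`, `c` and
#'   `effect_score` (the implied horizon mean).
#' @export
default_burden_curves <- function() {
  target <- c(SCC = 6.5, SCC_AT = 6.9, NP = 5.2, NP_DSS = 5.3,
              COMPLETE_SCH = 4.5)
  b <- 0.06
  cc <- -0.003
  horizon <- 26
  # horizon mean of a + b t + c t^2 over [0, T] is a + b T/2 + c T^2/3
  shape_mean <- b * horizon / 2 + cc * horizon^2 / 3
  data.frame(
    arm = sch_arms(),
    a = unname(target[sch_arms()] - shape_mean),
    b = b,
    c = cc,
    effect_score = unname(target[sch_arms()]),
    stringsAsFactors = FALSE
  )
}

#' Evaluate a quadratic burden curve
#'
#' @param coef numeric length-3 vector `(a, b, c)` of S(t) = a + b*t + c*t^2.
#' @param t time in weeks.
#' @return Burden score at `t`, clipped to the 0-10 scale.
#' @export
eval_burden_curve <- function(coef, t) {
  stopifnot(length(coef) == 3L, is.numeric(t))
  pmin(10, pmax(0, coef[[1]] + coef[[2]] * t + coef[[3]] * t^2))
}
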