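# Calibration: estimate model inputs (weekly utilization parameters and
# symptom-burden trajectories) from patient-level records, and convert
# means/SDs into the beta/gamma distributions the PSA draws from.

#' Estimate weekly utilization parameters for one arm
#'
#' Recovers the model's utilization inputs from patient-level records:
#' the weekly likelihood of any ED visit (mean over patients of each
#' patient's proportion of study weeks with at least one visit, with the
#' across-patient SD), the mean visit multiplicity per event-week (total
#' visits divided by event-weeks), the same two quantities for unplanned
#' hospitalization, and the mean length of stay per hospitalization.
#'
#' When no patient in the arm has an event, the conditional fields are
#' `NA` (missing, not zero) and flagged via the `missing_conditional`
#' attribute.
#'
#' @param trial An `sch_trial` object (see [generate_trial()]), or any list
#'   with compatible `patients` and `events` tables.
#' @param arm Arm identifier.
#' @return One-row `data.frame` with the columns of [default_utilization()].
#' @export
estimate_utilization <- function(trial, arm) {
  assert_arm(arm)
  p <- trial$patients[trial$patients$arm == arm, , drop = FALSE]
  if (!nrow(p)) stop("no records for arm ", arm, call. = FALSE)
  e <- trial$events[trial$events$patient_id %in% p$patient_id, , drop = FALSE]

  weeks <- p$weeks_on_study
  names(weeks) <- p$patient_id

  per_patient_prop <- function(any_event_pid) {
    k <- table(factor(any_event_pid, levels = p$patient_id))
    as.numeric(k) / as.numeric(weeks[p$patient_id])
  }
  ed_weeks <- e$patient_id[e$ed_visits > 0]
  hosp_weeks <- e$patient_id[e$hospitalizations > 0]
  prop_ed <- per_patient_prop(ed_weeks)
  prop_hosp <- per_patient_prop(hosp_weeks)

  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0

  n_ed <- n_ed_sd <- n_hosp <- n_hosp_sd <- los <- los_sd <- NA_real_
  missing_cond <- character()
  if (length(ed_weeks)) {
    cnt <- e$ed_visits[e$ed_visits > 0]
    n_ed <- mean(cnt); n_ed_sd <- sd0(cnt)
  } else missing_cond <- c(missing_cond, "n_ed")
  if (length(hosp_weeks)) {
    hcnt <- e$hospitalizations[e$hospitalizations > 0]
    n_hosp <- mean(hcnt); n_hosp_sd <- sd0(hcnt)
    per_stay_mean <- e$los_days[e$hospitalizations > 0] / hcnt
    los <- sum(e$los_days) / sum(hcnt)
    los_sd <- sd0(per_stay_mean)
  } else missing_cond <- c(missing_cond, "n_hosp", "los")

  out <- data.frame(
    arm = arm, n_patients = nrow(p),
    p_ed = mean(prop_ed), p_ed_sd = sd0(prop_ed),
    n_ed = n_ed, n_ed_sd = n_ed_sd,
    p_hosp = mean(prop_hosp), p_hosp_sd = sd0(prop_hosp),
    n_hosp = n_hosp, n_hosp_sd = n_hosp_sd,
    los = los, los_sd = los_sd,
    stringsAsFactors = FALSE
  )
  attr(out, "missing_conditional") <- missing_cond
  out
}

#' Weekly mean symptom-burden scores for one arm
#'
#' The daily burden is the mean of the 11 symptom severities (0-10). For
#' each study week (7 consecutive study days, weeks 1-26), each patient
#' contributes the mean daily burden over their reported days in that week;
#' the weekly score averages those contributions across patients. Weeks
#' with no reported day anywhere in the arm are `NA`.
#'
#' @inheritParams estimate_utilization
#' @return Numeric vector of length 26 (possibly with `NA` weeks).
#' @export
weekly_burden <- function(trial, arm) {
  assert_arm(arm)
  if (is.null(trial$reports)) stop("trial has no daily reports", call. = FALSE)
  pids <- trial$patients$patient_id[trial$patients$arm == arm]
  r <- trial$reports[trial$reports$patient_id %in% pids & trial$reports$reported, ,
                     drop = FALSE]
  if (!nrow(r)) stop("no reported days for arm ", arm, call. = FALSE)
  burden <- rowMeans(as.matrix(r[, paste0("s", sprintf("%02d", 1:11))]))
  week <- pmin(26L, as.integer(ceiling(r$day / 7)))
  key <- paste(r$patient_id, week)
  pw <- rowsum(cbind(burden, 1), key)
  pw_mean <- pw[, 1] / pw[, 2]
  pw_week <- as.integer(sub("^.* ", "", rownames(pw)))
  wk <- rowsum(cbind(pw_mean, 1), pw_week)
  out <- rep(NA_real_, 26)
  out[as.integer(rownames(wk))] <- wk[, 1] / wk[, 2]
  out
}

#' Fit a quadratic burden curve and its horizon-mean effectiveness
#'
#' Least-squares fit of S(t) = a + b*t + c*t^2 to the weekly scores
#' (t = week index), after linear interpolation of internal missing weeks;
#' leading/trailing missing weeks are dropped (and reported via the
#' `trailing_missing` attribute). The effectiveness score is the horizon
#' mean of the fitted curve, (1/T) * integral of S over [0, T], clipped to
#' the 0-10 scale — lower is better.
#'
#' @param weekly_scores Numeric vector of weekly mean burden scores
#'   (length <= horizon; `NA` for missing weeks).
#' @param horizon Model horizon T in weeks (default 26).
#' @return List with `coef` (a, b, c), `effect_score`, and `weekly` (the
#'   scores after interpolation).
#' @export
#' @examples
#' fit_quadratic_effect(rep(5, 26))$effect_score   # 5
fit_quadratic_effect <- function(weekly_scores, horizon = 26) {
  s <- as.numeric(weekly_scores)
  t <- seq_along(s)
  obs <- which(!is.na(s))
  if (length(obs) < 3) stop("need at least 3 non-missing weekly scores", call. = FALSE)
  # interpolate internal gaps only; edges stay missing
  filled <- s
  inner <- seq(min(obs), max(obs))
  filled[inner] <- stats::approx(t[obs], s[obs], xout = inner)$y
  use <- which(!is.na(filled))
  fit <- stats::lm.fit(cbind(1, t[use], t[use]^2), filled[use])
  cf <- unname(fit$coefficients)
  cf[is.na(cf)] <- 0
  effect <- cf[1] + cf[2] * horizon / 2 + cf[3] * horizon^2 / 3
  out <- list(coef = cf, effect_score = min(10, max(0, effect)), weekly = filled)
  attr(out, "trailing_missing") <- sum(is.na(filled))
  out
}

#' Beta distribution from a mean and SD
#'
#' Method-of-moments parameterization used for PSA draws of transition
#' probabilities: alpha = m*nu, beta = (1-m)*nu with
#' nu = m(1-m)/sd^2 - 1. An SD of 0 yields a point mass. If the SD is
#' infeasibly large (sd^2 >= m(1-m)), it is shrunk to
#' 0.95*sqrt(m(1-m)) with a warning so the PSA stays runnable.
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation (>= 0).
#' @return A list of class `dist_params` with `kind`, `alpha`, `beta`,
#'   `mean`, `sd`, `degenerate`.
#' @export
#' @examples
#' beta_from_moments(0.2, 0.1)   # alpha 3, beta 12
beta_from_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1) {
    stop("mean must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.finite(sd) || sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (sd == 0) {
    return(structure(list(kind = "beta", alpha = NA_real_, beta = NA_real_,
                          mean = mean, sd = 0, degenerate = TRUE),
                     class = "dist_params"))
  }
  vmax <- mean * (1 - mean)
  if (sd^2 >= vmax) {
    sd_new <- 0.95 * sqrt(vmax)
    warning(sprintf("sd %.4g infeasible for a beta with mean %.4g; shrunk to %.4g",
                    sd, mean, sd_new), call. = FALSE)
    sd <- sd_new
  }
  nu <- vmax / sd^2 - 1
  structure(list(kind = "beta", alpha = mean * nu, beta = (1 - mean) * nu,
                 mean = mean, sd = sd, degenerate = FALSE),
            class = "dist_params")
}

#' Gamma distribution from a mean and SD
#'
#' Method-of-moments parameterization used for PSA draws of costs,
#' conditional visit-count excesses and lengths of stay:
#' shape = (m/sd)^2, scale = sd^2/m. An SD of 0 yields a point mass.
#'
#' @param mean Positive mean.
#' @param sd Standard deviation (>= 0).
#' @return A list of class `dist_params` with `kind`, `shape`, `scale`,
#'   `mean`, `sd`, `degenerate`.
#' @export
gamma_from_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0) stop("mean must be > 0", call. = FALSE)
  if (!is.finite(sd) || sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (sd == 0) {
    return(structure(list(kind = "gamma", shape = NA_real_, scale = NA_real_,
                          mean = mean, sd = 0, degenerate = TRUE),
                     class = "dist_params"))
  }
  structure(list(kind = "gamma", shape = (mean / sd)^2, scale = sd^2 / mean,
                 mean = mean, sd = sd, degenerate = FALSE),
            class = "dist_params")
}

#' Draw from fitted PSA distribution parameters
#'
#' @param dp A `dist_params` object.
#' @param n Number of draws.
#' @return Numeric vector of `n` draws (constant at the mean for a
#'   degenerate distribution).
#' @export
draw_dist <- function(dp, n) {
  stopifnot(inherits(dp, "dist_params"))
  if (dp$degenerate) return(rep(dp$mean, n))
  switch(dp$kind,
    beta = stats::rbeta(n, dp$alpha, dp$beta),
    gamma = stats::rgamma(n, shape = dp$shape, scale = dp$scale),
    stop("unknown distribution kind ", dp$kind, call. = FALSE)
  )
}

#' Per-patient intervention cost of an arm
#'
#' Returns the configured per-patient intervention cost; with
#' `include_development = FALSE` the per-patient development share is
#' removed, leaving the arm's labor/operations component.
#'
#' @param arm Arm identifier.
#' @param costs A `cost_inputs` list, see [default_costs()].
#' @param include_development Include the per-patient development share?
#' @return Cost in dollars per patient.
#' @export
#' @examples
#' intervention_cost("NP_DSS", default_costs())                              # 1343
#' intervention_cost("NP_DSS", default_costs(), include_development = FALSE) # 90
intervention_cost <- function(arm, costs = default_costs(),
                              include_development = TRUE) {
  assert_arm(arm)
  base <- costs$intervention_cost_per_patient[[arm]]
  if (include_development) base else base - costs$dev_per_patient
}

#' Calibrate all model inputs from a trial
#'
#' Runs [estimate_utilization()], [weekly_burden()] and
#' [fit_quadratic_effect()] for every arm present.
#'
#' @param trial An `sch_trial` object.
#' @param horizon Horizon in weeks for the effectiveness integral.
#' @return List with `utilization` (data.frame, one row per arm) and
#'   `trajectories` (named list of [fit_quadratic_effect()] results).
#' @export
calibrate_trial <- function(trial, horizon = 26) {
  arms <- intersect(sch_arms(), unique(trial$patients$arm))
  util <- do.call(rbind, lapply(arms, estimate_utilization, trial = trial))
  traj <- NULL
  if (!is.null(trial$reports)) {
    traj <- lapply(arms, function(a) {
      fit_quadratic_effect(weekly_burden(trial, a), horizon = horizon)
    })
    names(traj) <- arms
  }
  list(utilization = util, trajectories = traj)
}
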