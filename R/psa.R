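# Second-order probabilistic sensitivity analysis: beta draws for weekly
# event probabilities, gamma draws for unit costs, conditional visit-count
# excesses and lengths of stay; symptom-burden scores are held constant
# across draws. Acceptability is summarized as cost-effectiveness
# acceptability curves over a willingness-to-pay grid.

#' Fit PSA sampling distributions from utilization and cost inputs
#'
#' Builds, for each arm, beta distributions (method of moments) for the
#' weekly ED and hospitalization probabilities and gamma distributions for
#' the conditional count excesses (count - 1, preserving the >= 1 support)
#' and length of stay; plus shared gamma distributions for the two unit
#' costs. Intervention and development costs carry no printed uncertainty
#' and stay fixed.
#'
#' @param utilization `data.frame` as [default_utilization()].
#' @param costs A `cost_inputs` list.
#' @return List with `arms` (per-arm named lists of `dist_params`) and
#'   `unit` (`c_ed_visit`, `c_night`).
#' @export
build_psa_dists <- function(utilization = default_utilization(),
                            costs = default_costs()) {
  shifted_gamma <- function(mean, sd) {
    if (mean <= 1 || sd == 0) {
      # no excess to vary: point mass at the mean
      structure(list(kind = "gamma", shape = NA_real_, scale = NA_real_,
                     mean = mean - 1, sd = 0, degenerate = TRUE),
                class = "dist_params")
    } else {
      gamma_from_moments(mean - 1, sd)
    }
  }
  arms <- lapply(seq_len(nrow(utilization)), function(i) {
    u <- utilization[i, ]
    list(
      p_ed = beta_from_moments(u$p_ed, u$p_ed_sd),
      n_ed_excess = shifted_gamma(u$n_ed, u$n_ed_sd),
      p_hosp = beta_from_moments(u$p_hosp, u$p_hosp_sd),
      n_hosp_excess = shifted_gamma(u$n_hosp, u$n_hosp_sd),
      los = gamma_from_moments(u$los, u$los_sd)
    )
  })
  names(arms) <- utilization$arm
  list(
    arms = arms,
    unit = list(
      c_ed_visit = gamma_from_moments(costs$c_ed_visit, costs$c_ed_visit_sd),
      c_night = gamma_from_moments(costs$c_night, costs$c_night_sd)
    )
  )
}

#' Draw PSA parameter realizations
#'
#' `n` independent joint draws of every varied parameter: per-arm
#' probabilities, conditional counts (1 + gamma excess) and LOS, and the
#' unit costs (drawn once per realization, shared across arms — they are
#' national unit prices, not arm properties).
#'
#' @param dists Output of [build_psa_dists()].
#' @param n Number of draws.
#' @param seed Integer seed (required).
#' @return List with `unit` (`data.frame` of `c_ed_visit`, `c_night`) and
#'   `arms` (named list of `data.frame`s with `p_ed`, `n_ed`, `p_hosp`,
#'   `n_hosp`, `los`), each with `n` rows.
#' @export
draw_psa_inputs <- function(dists, n, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("draw_psa_inputs() requires an explicit seed", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    unit <- data.frame(
      c_ed_visit = draw_dist(dists$unit$c_ed_visit, n),
      c_night = draw_dist(dists$unit$c_night, n)
    )
    arms <- lapply(dists$arms, function(d) {
      data.frame(
        p_ed = draw_dist(d$p_ed, n),
        n_ed = 1 + draw_dist(d$n_ed_excess, n),
        p_hosp = draw_dist(d$p_hosp, n),
        n_hosp = 1 + draw_dist(d$n_hosp_excess, n),
        los = draw_dist(d$los, n)
      )
    })
    list(unit = unit, arms = arms)
  })
}

#' Run the probabilistic sensitivity analysis
#'
#' `config$psa_outer` second-order draws of all varied parameters; for each
#' draw, the per-arm cost comes from the closed-form weekly expectation
#' (default) or from a `config$psa_inner`-patient microsimulation.
#' Effectiveness is held at the calibrated score in every draw.
#'
#' @inheritParams base_case
#' @param config A [model_config()]; `seed` must be set (or supply `seed`).
#' @param seed Optional seed overriding `config$seed`.
#' @return List of class `psa_result`: `draws` (long `data.frame` with
#'   `draw`, `arm`, `cost`, `effect`), `summary` (per-arm mean cost/effect
#'   and Monte Carlo SE), `seed`, `config`.
#' @export
run_psa <- function(utilization = default_utilization(),
                    costs = default_costs(),
                    effects = default_burden_curves(),
                    config = model_config(), seed = config$seed) {
  if (is.null(seed)) stop("run_psa() requires a seed (config$seed or seed=)",
                          call. = FALSE)
  if (is.data.frame(effects)) {
    effects <- stats::setNames(effects$effect_score, effects$arm)
  }
  K <- config$psa_outer
  dists <- build_psa_dists(utilization, costs)
  draws_in <- draw_psa_inputs(dists, K, seed)

  per_arm <- lapply(utilization$arm, function(arm) {
    d <- draws_in$arms[[arm]]
    iv <- intervention_cost(arm, costs, config$include_development)
    if (!config$psa_inner_microsim) {
      m_ed <- if (config$visit_multiplier) d$n_ed else 1
      m_h <- if (config$visit_multiplier) d$n_hosp else 1
      cost <- config$horizon *
        (d$p_ed * m_ed * draws_in$unit$c_ed_visit +
           d$p_hosp * m_h * draws_in$unit$c_night * d$los) + iv
    } else {
      cfg_inner <- config
      cfg_inner$cohort_size <- config$psa_inner
      cost <- vapply(seq_len(K), function(k) {
        ck <- costs
        ck$c_ed_visit <- draws_in$unit$c_ed_visit[k]
        ck$c_night <- draws_in$unit$c_night[k]
        uk <- c(list(arm = arm), as.list(d[k, ]), los_sd = 0)
        run_cohort_simulation(uk, ck, effects[[arm]], cfg_inner,
                              seed = (seed + k) %% .Machine$integer.max)$cost
      }, numeric(1))
    }
    data.frame(draw = seq_len(K), arm = arm, cost = cost,
               effect = effects[[arm]], stringsAsFactors = FALSE)
  })
  draws <- do.call(rbind, per_arm)
  summ <- do.call(rbind, lapply(split(draws, draws$arm), function(g) {
    data.frame(arm = g$arm[1], mean_cost = mean(g$cost),
               se_cost = stats::sd(g$cost) / sqrt(nrow(g)),
               effect = g$effect[1], stringsAsFactors = FALSE)
  }))
  summ <- summ[match(utilization$arm, summ$arm), ]
  rownames(summ) <- NULL
  structure(list(draws = draws, summary = summ, seed = as.integer(seed),
                 config = config),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("PSA:", x$config$psa_outer, "second-order draws (seed", x$seed, ")\n")
  print(x$summary, ...)
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp * (anchor - effect_score) - cost`: the dollar value of the burden
#' reduction achieved relative to the worst possible score, minus cost.
#' Pairwise NMB differences do not depend on the anchor.
#'
#' @param cost Cost in dollars.
#' @param effect_score Burden score (0-10, lower better).
#' @param wtp Willingness to pay, dollars per 1-point burden reduction
#'   (>= 0).
#' @param anchor Worst-score anchor; fixed at 10 by default.
#' @return NMB in dollars (vectorized).
#' @export
nmb <- function(cost, effect_score, wtp, anchor = 10) {
  if (any(wtp < 0)) stop("wtp must be >= 0", call. = FALSE)
  wtp * (anchor - effect_score) - cost
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay threshold, the fraction of PSA draws in
#' which each arm attains the maximal net monetary benefit (exact ties
#' split equally), so the probabilities sum to 1 across arms at every
#' threshold.
#'
#' @param psa A `psa_result` from [run_psa()].
#' @param wtp_grid Thresholds in dollars per 1-point burden reduction;
#'   defaults to the grid in the PSA's config.
#' @return `data.frame` of class `ceac_curve` in long format: `wtp`,
#'   `arm`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = psa$config$wtp_grid) {
  stopifnot(inherits(psa, "psa_result"))
  if (!length(wtp_grid)) stop("wtp_grid must be non-empty", call. = FALSE)
  arms <- unique(psa$draws$arm)
  K <- max(psa$draws$draw)
  # reshape long -> K x arms cost matrix (draws are stacked per arm)
  cost <- vapply(arms, function(a) psa$draws$cost[psa$draws$arm == a],
                 numeric(K))
  red <- vapply(arms, function(a) 10 - psa$draws$effect[psa$draws$arm == a][1],
                numeric(1))
  out <- do.call(rbind, lapply(wtp_grid, function(l) {
    benefit <- sweep(-cost, 2, l * red, "+")     # K x arms NMB matrix
    best <- matrixStats_rowMaxs(benefit)
    win <- benefit >= best - 1e-9 * pmax(1, abs(best))
    share <- win / rowSums(win)
    data.frame(wtp = l, arm = arms, probability = colMeans(share),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("ceac_curve", class(out))
  out
}

# row maxima without a matrixStats dependency
matrixStats_rowMaxs <- function(m) do.call(pmax, as.data.frame(m))

#' Plot a cost-effectiveness acceptability curve
#'
#' @param x A `ceac_curve` from [ceac()].
#' @param ... Unused.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot.ceac_curve <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting CEACs", call. = FALSE)
  }
  ggplot2::ggplot(x, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                  colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay ($ per 1-point burden reduction)",
                  y = "Probability cost-effective", colour = "Strategy") +
    ggplot2::theme_minimal()
}
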