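# Incremental cost-effectiveness: ICERs, absolute and extended dominance,
# and the efficiency frontier over strategy outcomes. Effectiveness is the
# symptom-burden score (lower is better); internally strategies are
# compared on burden reduction relative to the fixed worst-score anchor of
# 10, so ICERs are dollars per 1-point burden reduction and are invariant
# to the anchor.

#' Incremental cost-effectiveness ratio between two strategies
#'
#' `(cost_b - cost_a) / (effect_a - effect_b)`: the extra cost of strategy
#' `b` per 1-point reduction in burden score relative to `a`. Requires `b`
#' to be strictly more effective (lower burden) than `a`; equal effects
#' have no defined ratio and signal a dominance comparison instead.
#'
#' @param a,b One-row strategy outcomes (`cost`, `effect`) — `a` the
#'   comparator, `b` the more effective strategy.
#' @return Dollars per 1-point burden reduction.
#' @export
#' @examples
#' icer(list(cost = 14590, effect = 5.3), list(cost = 18200, effect = 4.5))
icer <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  if (b$effect >= a$effect) {
    stop("icer(): b must be strictly more effective (lower burden) than a; ",
         "equal effects call for a dominance comparison", call. = FALSE)
  }
  (b$cost - a$cost) / (a$effect - b$effect)
}

#' Efficiency frontier with absolute and extended dominance
#'
#' Classifies every strategy as `reference` (least costly non-dominated),
#' `on_frontier`, `absolutely_dominated` (at least as costly and at least
#' as burdensome as some other strategy, strictly worse in one; exact ties
#' are broken deterministically against the later-sorted arm) or
#' `extendedly_dominated` (its incremental ICER exceeds that of the next
#' more effective frontier strategy, so a mix of its neighbours dominates
#' it). Frontier ICERs are incremental between adjacent frontier
#' strategies and strictly increase with cost.
#'
#' @param outcomes `data.frame` of strategy outcomes with `arm`, `cost`,
#'   `effect` columns (one row per distinct arm).
#' @return `data.frame` sorted by cost with columns `arm`, `cost`,
#'   `effect`, `status`, `icer` (`NA` for the reference and dominated
#'   strategies).
#' @export
#' @examples
#' find_frontier(base_case())
find_frontier <- function(outcomes) {
  stopifnot(is.data.frame(outcomes), nrow(outcomes) >= 1)
  if (anyDuplicated(outcomes$arm)) stop("duplicate arms in outcomes", call. = FALSE)
  x <- outcomes[order(outcomes$cost, outcomes$effect, outcomes$arm),
                c("arm", "cost", "effect")]
  rownames(x) <- NULL
  n <- nrow(x)
  red <- 10 - x$effect     # burden reduction vs fixed anchor

  status <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if ((x$cost[j] < x$cost[i] && red[j] >= red[i]) ||
          (x$cost[j] <= x$cost[i] && red[j] > red[i]) ||
          (x$cost[j] == x$cost[i] && red[j] == red[i] && j < i)) {
        status[i] <- "absolutely_dominated"
        break
      }
    }
  }

  surv <- which(is.na(status))     # already sorted by cost = by reduction
  repeat {
    if (length(surv) <= 2) break
    icers <- diff(x$cost[surv]) / diff(red[surv])
    bad <- which(diff(icers) <= 0)     # icer_k >= icer_{k+1}
    if (!length(bad)) break
    drop <- surv[bad[1] + 1]           # the middle strategy of the violating triple
    status[drop] <- "extendedly_dominated"
    surv <- setdiff(surv, drop)
  }

  icer_col <- rep(NA_real_, n)
  status[surv[1]] <- "reference"
  if (length(surv) > 1) {
    status[surv[-1]] <- "on_frontier"
    icer_col[surv[-1]] <- diff(x$cost[surv]) / diff(red[surv])
  }
  x$status <- status
  x$icer <- icer_col
  x
}

#' Table-style frontier report
#'
#' Runs the deterministic base case and frontier for both cost variants
#' (including and excluding the development share).
#'
#' @inheritParams base_case
#' @return List with `including_development` and `excluding_development`
#'   frontier tables.
#' @export
frontier_report <- function(utilization = default_utilization(),
                            costs = default_costs(),
                            effects = default_burden_curves(),
                            config = model_config()) {
  cfg_excl <- config
  cfg_excl$include_development <- FALSE
  cfg_incl <- config
  cfg_incl$include_development <- TRUE
  list(
    including_development =
      find_frontier(base_case(utilization, costs, effects, cfg_incl)),
    excluding_development =
      find_frontier(base_case(utilization, costs, effects, cfg_excl))
  )
}
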