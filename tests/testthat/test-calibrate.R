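test_that("utilization estimates match a hand count on a two-patient fixture", {
  u <- estimate_utilization(tiny_trial(), "SCC")
  # A: 1 ED event-week of 4 study weeks (0.25), B: 0/4 -> mean 0.125
  expect_equal(u$p_ed, 0.125)
  expect_equal(u$p_ed_sd, sd(c(0.25, 0)))
  expect_equal(u$n_ed, 2)             # 2 visits in A's single ED event-week
  expect_equal(u$p_hosp, 0.125)
  expect_equal(u$n_hosp, 1)
  expect_equal(u$los, 3)
  expect_error(estimate_utilization(tiny_trial(), "NP"), "no records")
})

test_that("an arm without events yields zero probabilities and flagged missing conditionals", {
  tr <- tiny_trial()
  tr$events <- tr$events[0, ]
  u <- estimate_utilization(tr, "SCC")
  expect_equal(u$p_ed, 0)
  expect_equal(u$p_hosp, 0)
  expect_true(is.na(u$n_ed) && is.na(u$n_hosp) && is.na(u$los))
  expect_setequal(attr(u, "missing_conditional"), c("n_ed", "n_hosp", "los"))
})

test_that("weekly burden averages daily scores within week, then across patients", {
  expect_equal(weekly_burden(constant_burden_trial(0), "SCC"), rep(0, 26))
  expect_equal(weekly_burden(constant_burden_trial(5), "SCC"), rep(5, 26))
  expect_equal(weekly_burden(constant_burden_trial(c(4, 6)), "SCC"), rep(5, 26))
})

test_that("weeks with no reported day are missing, not zero", {
  tr <- constant_burden_trial(5)
  tr$reports$reported[tr$reports$day > 7 & tr$reports$day <= 14] <- FALSE
  w <- weekly_burden(tr, "SCC")
  expect_true(is.na(w[2]))
  expect_equal(w[-2], rep(5, 25))
})

test_that("quadratic fit recovers exact curves and closed-form horizon means", {
  # constant curve: integral over any bounds / T equals the constant
  expect_equal(fit_quadratic_effect(rep(5, 26))$effect_score, 5)
  # linear curve 2 + 0.1 t over [0, 26]: mean = 2 + 0.1 * 13 = 3.3
  lin <- fit_quadratic_effect(2 + 0.1 * (1:26))
  expect_equal(lin$effect_score, 3.3, tolerance = 1e-10)
  # exact quadratic interpolation
  tq <- 1:26
  fit <- fit_quadratic_effect(1 + 0.2 * tq - 0.005 * tq^2)
  expect_equal(fit$coef, c(1, 0.2, -0.005), tolerance = 1e-8)
  expect_error(fit_quadratic_effect(c(1, 2, rep(NA, 24))), "at least 3")
})

test_that("internal missing weeks are interpolated and do not move an affine fit", {
  s <- 2 + 0.1 * (1:26)
  s[c(8, 9, 15)] <- NA
  fit <- fit_quadratic_effect(s)
  expect_equal(fit$effect_score, 3.3, tolerance = 1e-10)
  expect_equal(fit$weekly[8], 2.8, tolerance = 1e-12)
})

test_that("beta method of moments is exact and round-trips analytically", {
  d <- beta_from_moments(0.2, 0.1)
  expect_equal(d$alpha, 3)
  expect_equal(d$beta, 12)
  # round-trip on the SCC weekly ED likelihood (3.7% +- 7.9%)
  d2 <- beta_from_moments(0.037, 0.079)
  m <- d2$alpha / (d2$alpha + d2$beta)
  v <- d2$alpha * d2$beta / ((d2$alpha + d2$beta)^2 * (d2$alpha + d2$beta + 1))
  expect_equal(m, 0.037, tolerance = 1e-9)
  expect_equal(sqrt(v), 0.079, tolerance = 1e-9)
  expect_true(beta_from_moments(0.3, 0)$degenerate)
  expect_error(beta_from_moments(1.2, 0.1), "\\(0, 1\\)")
  expect_warning(beta_from_moments(0.5, 0.6), "shrunk")
})

test_that("gamma method of moments is exact and round-trips analytically", {
  d <- gamma_from_moments(3574, 122)
  expect_equal(d$shape, (3574 / 122)^2)
  expect_equal(d$shape, 858.2, tolerance = 1e-3)
  expect_equal(d$scale, 122^2 / 3574)
  expect_equal(d$scale, 4.1645, tolerance = 1e-4)
  expect_equal(d$shape * d$scale, 3574, tolerance = 1e-9)
  expect_equal(sqrt(d$shape) * d$scale, 122, tolerance = 1e-9)
  expect_true(gamma_from_moments(10, 0)$degenerate)
  expect_error(gamma_from_moments(-1, 2), "> 0")
})

test_that("fitted distributions reproduce source moments across random inputs", {
  withr::with_seed(31, {
    for (i in 1:25) {
      m <- runif(1, 0.01, 0.99)
      s <- runif(1, 1e-4, 0.9 * sqrt(m * (1 - m)))
      d <- beta_from_moments(m, s)
      expect_equal(d$alpha / (d$alpha + d$beta), m, tolerance = 1e-9)
      mg <- runif(1, 0.1, 5000)
      sg <- runif(1, 1e-3, mg)
      g <- gamma_from_moments(mg, sg)
      expect_equal(g$shape * g$scale, mg, tolerance = 1e-9)
      expect_equal(sqrt(g$shape) * g$scale, sg, tolerance = 1e-9)
    }
  })
})

test_that("intervention costs reproduce the per-patient inputs", {
  costs <- default_costs()
  expect_equal(intervention_cost("SCC", costs), 1253)
  expect_equal(intervention_cost("NP", costs), 1309)
  expect_equal(intervention_cost("NP_DSS", costs), 1343)
  expect_equal(intervention_cost("COMPLETE_SCH", costs), 1340)
  # labor/operations component once the development share is stripped
  expect_equal(intervention_cost("NP_DSS", costs, include_development = FALSE), 90)
  expect_equal(intervention_cost("SCC", costs, include_development = FALSE), 0)
})
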