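zero_sd_utilization <- function() {
  u <- default_utilization()
  u[, grepl("_sd$", names(u))] <- 0
  u
}

zero_sd_costs <- function() {
  costs <- default_costs()
  costs$c_ed_visit_sd <- 0
  costs$c_night_sd <- 0
  costs
}

test_that("degenerate distributions draw their means exactly", {
  dists <- build_psa_dists(zero_sd_utilization(), zero_sd_costs())
  d <- draw_psa_inputs(dists, 10, seed = 1)
  expect_equal(unique(d$unit$c_night), 3574)
  expect_equal(unique(d$arms$SCC$p_ed), 0.037)
  expect_equal(unique(d$arms$NP_DSS$n_ed), 2.1)
  expect_equal(unique(d$arms$NP_DSS$los), 3.6)
})

test_that("PSA draws are seeded and reproducible", {
  dists <- build_psa_dists()
  expect_error(draw_psa_inputs(dists, 5), "seed")
  expect_identical(draw_psa_inputs(dists, 50, seed = 3),
                   draw_psa_inputs(dists, 50, seed = 3))
  p1 <- run_psa(config = model_config(psa_outer = 40, seed = 6))
  p2 <- run_psa(config = model_config(psa_outer = 40, seed = 6))
  expect_identical(p1, p2)
  expect_error(run_psa(config = model_config()), "seed")
})

test_that("sampled unit-cost moments match the gamma source", {
  dists <- build_psa_dists()
  d <- draw_psa_inputs(dists, 1e5, seed = 17)
  expect_lt(abs(mean(d$unit$c_night) - 3574), 3 * 122 / sqrt(1e5))
  expect_lt(abs(mean(d$unit$c_ed_visit) - 1135), 3 * 33 / sqrt(1e5))
  expect_lt(abs(sd(d$unit$c_night) - 122), 5)
})

test_that("sampled probabilities and shifted counts keep their support and means", {
  dists <- build_psa_dists()
  d <- draw_psa_inputs(dists, 2e4, seed = 23)
  for (arm in sch_arms()) {
    a <- d$arms[[arm]]
    expect_true(all(a$p_ed >= 0 & a$p_ed <= 1))
    expect_true(all(a$p_hosp >= 0 & a$p_hosp <= 1))
    expect_true(all(a$n_ed >= 1 & a$n_hosp >= 1))
    expect_true(all(a$los > 0))
  }
  u <- default_utilization()
  a <- d$arms$NP_DSS
  i <- which(u$arm == "NP_DSS")
  expect_lt(abs(mean(a$n_ed) - u$n_ed[i]), 3 * u$n_ed_sd[i] / sqrt(2e4))
  expect_lt(abs(mean(a$p_ed) - u$p_ed[i]), 3 * u$p_ed_sd[i] / sqrt(2e4))
})

test_that("zero-SD PSA collapses every draw to the base case", {
  cfg <- model_config(psa_outer = 25, seed = 2)
  psa <- run_psa(zero_sd_utilization(), zero_sd_costs(),
                 default_burden_curves(), cfg)
  bc <- base_case(zero_sd_utilization(), zero_sd_costs(),
                  default_burden_curves(), cfg)
  for (arm in sch_arms()) {
    expect_equal(unique(psa$draws$cost[psa$draws$arm == arm]),
                 bc$cost[bc$arm == arm])
  }
  expect_equal(psa$summary$mean_cost, bc$cost)
})

test_that("PSA mean costs are unbiased for the deterministic base case", {
  cfg <- model_config(psa_outer = 1000, seed = 12)
  psa <- run_psa(config = cfg)
  bc <- base_case(config = cfg)
  for (i in 1:5) {
    expect_lt(abs(psa$summary$mean_cost[i] - bc$cost[i]),
              3 * psa$summary$se_cost[i])
  }
})

test_that("the microsimulation inner loop agrees with the closed-form inner loop", {
  closed <- run_psa(config = model_config(psa_outer = 20, seed = 3))
  micro <- run_psa(config = model_config(psa_outer = 20, psa_inner = 500,
                                         psa_inner_microsim = TRUE, seed = 3))
  # same outer parameter draws; the inner loop only adds first-order noise
  expect_equal(micro$summary$mean_cost, closed$summary$mean_cost,
               tolerance = 0.05)
  expect_equal(micro$summary$effect, closed$summary$effect)
})

test_that("net monetary benefit values burden reduction against the fixed anchor", {
  expect_equal(nmb(500, 4.5, 0), -500)
  expect_equal(nmb(18200, 4.5, 1000), 1000 * 5.5 - 18200)
  expect_equal(nmb(18200, 4.5, 1000), -12700)
  expect_error(nmb(100, 5, -10), ">= 0")
  # anchor shifts cancel in pairwise differences
  d1 <- nmb(100, 6, 500) - nmb(200, 4, 500)
  d2 <- nmb(100, 6, 500, anchor = 7) - nmb(200, 4, 500, anchor = 7)
  expect_equal(d1, d2)
})

test_that("CEAC probabilities are proper and identify the deterministic winners", {
  cfg <- model_config(psa_outer = 30, seed = 5)
  psa0 <- run_psa(zero_sd_utilization(), zero_sd_costs(),
                  default_burden_curves(), cfg)
  cc <- ceac(psa0, wtp_grid = c(0, 10000, 20000))
  sums <- tapply(cc$probability, cc$wtp, sum)
  expect_equal(as.numeric(sums), rep(1, 3))
  # cheapest arm wins all draws at wtp 0
  expect_equal(cc$probability[cc$wtp == 0 & cc$arm == "NP_DSS"], 1)
  # far above the frontier ICER the most effective arm wins
  expect_equal(cc$probability[cc$wtp == 10000 & cc$arm == "COMPLETE_SCH"], 1)
  expect_equal(cc$probability[cc$wtp == 20000 & cc$arm == "COMPLETE_SCH"], 1)
})

test_that("CEAC columns always sum to one under sampled draws", {
  psa <- run_psa(config = model_config(psa_outer = 200, seed = 14))
  cc <- ceac(psa, wtp_grid = seq(0, 20000, 2500))
  sums <- tapply(cc$probability, cc$wtp, sum)
  expect_equal(as.numeric(sums), rep(1, length(unique(cc$wtp))))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
})

test_that("acceptability of the most effective arm rises toward one with wtp", {
  psa <- run_psa(config = model_config(psa_outer = 400, seed = 15))
  cc <- ceac(psa, wtp_grid = c(0, 5000, 50000, 1e7))
  p_sch <- cc$probability[cc$arm == "COMPLETE_SCH"]
  expect_lt(p_sch[1], p_sch[3] + 1e-12)
  expect_equal(p_sch[4], 1)   # effects constant across draws, so wtp -> Inf forces it
})
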