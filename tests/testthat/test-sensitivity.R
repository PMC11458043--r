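# One-way sensitivity analysis, probabilistic sensitivity analysis and
# acceptability curves.

test_that("one-way SA finds no threshold on the bundled parameter set", {
  sa <- one_way_sa(base_params())
  # one row per non-fixed parameter
  expect_equal(nrow(sa), sum(base_params()$table$dist != "fixed"))
  expect_false(any(sa$threshold))
  # deprescribing stays lower-cost and QALY-saving at both range ends
  expect_true(all(sa$dominance_at_low == "dominant"))
  expect_true(all(sa$dominance_at_high == "dominant"))
  expect_true(all(sa$cost_effective_at_low))
  expect_true(all(sa$cost_effective_at_high))
  # tornado order: spreads nonincreasing
  expect_true(all(diff(sa$spread) <= 0))
})

test_that("parameters without leverage fall to the bottom of the tornado", {
  # age has no published life-table link, so it cannot move any outcome
  sa <- one_way_sa(base_params())
  expect_equal(sa$spread[sa$parameter == "age_years"], 0)
  # a zero-width range yields zero spread and sorts last
  path <- modified_config(function(raw) {
    raw$utility$convalescence_pneumonia_days <-
      list(base = 31, low = 31, high = 31, dist = "triangular")
    raw
  })
  sa2 <- one_way_sa(load_parameters(path))
  expect_equal(sa2$spread[sa2$parameter == "convalescence_pneumonia_days"], 0)
  expect_true(which(sa2$parameter == "convalescence_pneumonia_days") >
                nrow(sa2) - sum(sa2$spread == 0))
})

test_that("tracked-outcome alternatives are consistent", {
  sa_nmb <- one_way_sa(base_params(), tracked = "nmb")
  base_inc <- attr(sa_nmb, "base_incremental")
  # NMB stays positive over every range end (no verdict change)
  expect_true(all(sa_nmb$outcome_at_low > 0))
  expect_true(all(sa_nmb$outcome_at_high > 0))
  expect_true(base_inc$cost_effective_at_wtp)
})

test_that("PSA is seeded and byte-reproducible", {
  params <- base_params()
  a <- run_psa(params, n_draws = 50, seed = 123)
  b <- run_psa(params, n_draws = 50, seed = 123)
  expect_identical(a$draws, b$draws)
  c2 <- run_psa(params, n_draws = 50, seed = 124)
  expect_false(identical(a$draws, c2$draws))
  # both strategies are evaluated on the same draw: common parameters mean
  # per-draw incremental columns are exact differences
  expect_equal(a$draws$incremental_cost,
               a$draws$cost_deprescribing - a$draws$cost_usual_care)
})

test_that("degenerate distributions reproduce the base case on every draw", {
  params <- degenerate_params()
  psa <- run_psa(params, n_draws = 5, seed = 1)
  base_inc <- ppicea:::.inc_from_values(param_values(params),
                                        wtp = params$run$wtp_threshold_usd)
  # bit-identical to the rollback at base values
  expect_identical(psa$draws$incremental_cost,
                   rep(base_inc$incremental_cost, 5))
  expect_identical(psa$draws$qaly_saved, rep(base_inc$qaly_saved, 5))
  # and equal to the enumerated base case
  fit <- decision_cea(params)
  expect_equal(psa$draws$incremental_cost[1],
               fit$incremental$incremental_cost, tolerance = 1e-12)
  expect_equal(psa$draws$qaly_saved[1], fit$incremental$qaly_saved,
               tolerance = 1e-12)
})

test_that("PSA summaries are recomputable from the per-draw vectors", {
  psa <- run_psa(base_params(), n_draws = 400, seed = 5)
  s <- summary(psa)
  d <- psa$draws
  expect_equal(s$qaly_saved[["mean"]], mean(d$qaly_saved))
  expect_equal(s$incremental_cost[["pct_ci_low"]],
               unname(quantile(d$incremental_cost, 0.025)))
  expect_equal(s$proportions[["qaly_saving"]], mean(d$qaly_saved > 0))
  expect_equal(s$proportions[["cost_saving"]], mean(d$incremental_cost < 0))
  expect_equal(s$proportions[["cost_effective_at_wtp"]],
               mean(d$nmb > 0))
  expect_true(all(s$proportions >= 0 & s$proportions <= 1))
})

test_that("Monte Carlo error of the PSA mean shrinks with draw count", {
  small <- summary(run_psa(base_params(), n_draws = 100, seed = 11))
  large <- summary(run_psa(base_params(), n_draws = 1600, seed = 11))
  hw <- function(s) (s[["mean_ci_high"]] - s[["mean_ci_low"]]) / 2
  ratio <- hw(small$qaly_saved) / hw(large$qaly_saved)
  # expected factor 4 at 16x the draws
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 6.5)
})

test_that("invalid adverse-event draws are rejected and resampled", {
  path <- modified_config(function(raw) {
    raw$clinical$p0_hypomag <- list(base = 0.30, low = 0.15, high = 0.45,
                                    dist = "beta")
    raw$clinical$p0_pneumonia <- list(base = 0.33, low = 0.18, high = 0.48,
                                      dist = "beta")
    raw$clinical$p0_cdi <- list(base = 0.30, low = 0.15, high = 0.45,
                                dist = "beta")
    raw
  })
  params <- load_parameters(path)
  psa <- run_psa(params, n_draws = 300, seed = 3)
  expect_gt(psa$n_rejected, 0)
  expect_equal(nrow(psa$draws), 300)
  expect_true(all(is.finite(psa$draws$incremental_cost)))
})

test_that("the acceptability curve matches the PSA proportions", {
  psa <- run_psa(base_params(), n_draws = 500, seed = 21)
  s <- summary(psa)
  # at the WTP threshold the CEAC equals the cost-effective proportion
  at_wtp <- ceac(psa, psa$wtp)
  expect_identical(at_wtp$probability_cost_effective,
                   s$proportions[["cost_effective_at_wtp"]])
  # WTP 0: proportion of cost-saving draws
  expect_identical(ceac(psa, 0)$probability_cost_effective,
                   s$proportions[["cost_saving"]])
  # WTP -> infinity: proportion of QALY-saving draws
  expect_equal(ceac(psa, 1e12)$probability_cost_effective,
               s$proportions[["qaly_saving"]])
  # nondecreasing when every draw saves QALYs
  if (all(psa$draws$qaly_saved >= 0)) {
    curve <- ceac(psa, seq(0, 1e5, length.out = 21))
    expect_true(all(diff(curve$probability_cost_effective) >= 0))
  }
  # single-draw PSA: step function in {0, 1}
  one <- run_psa(base_params(), n_draws = 1, seed = 2)
  expect_true(all(ceac(one, c(0, 1e4, 1e6))$probability_cost_effective
                  %in% c(0, 1)))
})
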