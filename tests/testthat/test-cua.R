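tab <- default_parameters()
means <- param_means(tab)

test_that("discounting follows the first-year-undiscounted convention", {
  expect_identical(discount_factor(1, 0.035), 1)
  expect_equal(discount_factor(2, 0.035), 1 / 1.035, tolerance = 1e-12)
  expect_identical(discount_factor(1:10, 0), rep(1, 10))
  expect_equal(discount_factor(1, 0.035, exponent = "t"), 1 / 1.035)
  expect_error(discount_factor(0, 0.035), ">= 1")
  expect_error(discount_factor(1, -0.01), "non-negative")
})

test_that("outcome accumulation matches hand arithmetic on degenerate traces", {
  # a cohort that is entirely dead accrues only the cycle-1 treatment cost
  dead <- constant_trace(c(0, 0, 0, 0, 0, 0, 1), 49, arm = "chemo")
  o <- accumulate_outcomes(dead, means, "chemo", "healthcare", 0.035)
  expect_equal(o$cost, 194900)
  expect_identical(o$ly, 0)
  expect_identical(o$qaly, 0)
  # two undiscounted cycles spent fully disease-free
  dfs <- constant_trace(c(1, 0, 0, 0, 0, 0, 0), 2, arm = "chemo")
  o2 <- accumulate_outcomes(dfs, means, "chemo", "healthcare", 0)
  expect_equal(o2$cost, 194900 + 2 * 9493)
  expect_equal(o2$ly, 2)
  expect_equal(o2$qaly, 2 * 0.832)
  # societal adds non-medical course and state costs
  o3 <- accumulate_outcomes(dfs, means, "chemo", "societal", 0)
  expect_equal(o3$cost, 194900 + 3494 + 2 * (9493 + 1747))
})

test_that("arm outcomes satisfy the accounting inequalities", {
  fit <- cua_model(tab)
  for (persp in c("healthcare", "societal")) {
    for (arm in c("trastuzumab", "chemo")) {
      o <- fit$outcomes[[persp]][[arm]]
      expect_lt(o$qaly, o$ly)             # utilities < 1
      expect_lte(o$cost, o$cost_undiscounted)
      expect_lte(o$ly, o$ly_undiscounted)
      expect_gt(o$cost, 0)
    }
    expect_gte(fit$outcomes$societal[[1]]$cost, fit$outcomes$healthcare[[1]]$cost)
  }
  # all utilities 1 makes QALYs equal life-years exactly
  v1 <- means
  v1[c("u_dfs", "u_chf", "u_rec", "u_met")] <- 1
  tr <- run_cohort(v1, "chemo")
  o <- accumulate_outcomes(tr, v1, "chemo", "healthcare", 0.035)
  expect_equal(o$qaly, o$ly, tolerance = 1e-12)
  # zero discount rate: discounted equals undiscounted exactly
  o0 <- accumulate_outcomes(tr, v1, "chemo", "healthcare", 0)
  expect_identical(o0$cost, o0$cost_undiscounted)
  expect_identical(o0$qaly, o0$qaly_undiscounted)
})

test_that("incremental results, dominance flags and NMB follow their definitions", {
  mk <- function(cost, qaly, ly = qaly) structure(
    list(cost = cost, ly = ly, qaly = qaly, arm = "x", perspective = "healthcare"),
    class = "arm_outcome")
  ce <- compute_icer(mk(1100, 3), mk(1000, 1))
  expect_equal(ce$icer_per_qaly, 50)
  expect_identical(ce$dominance, "none")
  ce0 <- compute_icer(mk(1000, 1), mk(1000, 1))
  expect_true(is.na(ce0$icer_per_qaly))
  expect_identical(compute_icer(mk(990, 2), mk(1000, 1))$dominance,
                   "intervention_dominant")
  expect_identical(compute_icer(mk(1100, 0.5), mk(1000, 1))$dominance,
                   "intervention_dominated")
  ce1 <- list(delta_cost = 453505, delta_qaly = 1)
  expect_equal(net_monetary_benefit(ce1, 453505), 0)
  expect_equal(net_monetary_benefit(ce1, 120000), -333505)
  expect_identical(net_monetary_benefit(list(delta_cost = 0, delta_qaly = 0), 5), 0)
})

test_that("a one-off cost added to both arms' treatment courses cancels in the ICER", {
  # (an annual state cost does not cancel, because the arms differ in
  # discounted time alive; the course cost is charged to the same unit
  # cohort in both arms)
  fit <- cua_model(tab)
  tab2 <- set_param(set_param(tab, "dmc_tx_trast",
                              mean = means[["dmc_tx_trast"]] + 5e4),
                    "dmc_tx_ct", mean = means[["dmc_tx_ct"]] + 5e4)
  fit2 <- cua_model(tab2)
  expect_equal(fit2$ce$healthcare$delta_cost, fit$ce$healthcare$delta_cost,
               tolerance = 1e-9)
  expect_equal(fit2$ce$healthcare$icer_per_qaly, fit$ce$healthcare$icer_per_qaly,
               tolerance = 1e-9)
})

test_that("threshold price is the NMB root, a fixed point at the current ICER, and monotone in lambda", {
  fit <- cua_model(tab)
  icer_now <- fit$ce$healthcare$icer_per_qaly
  # lambda at the current ICER returns the current course cost
  expect_equal(threshold_price(tab, lambda = icer_now),
               means[["dmc_tx_trast"]], tolerance = 1e-5)
  # at the returned price the NMB is zero within the bisection tolerance
  for (persp in c("healthcare", "societal")) {
    price <- threshold_price(tab, lambda = 120000, perspective = persp)
    tab_at <- set_param(tab, "dmc_tx_trast",
      mean = price - if (persp == "societal") means[["dnmc_tx_trast"]] else 0)
    nmb <- net_monetary_benefit(cua_model(tab_at)$ce[[persp]], 120000)
    expect_lt(abs(nmb), 1)
  }
  # strictly increasing in the willingness-to-pay threshold
  prices <- vapply(c(6e4, 1.2e5, 2.4e5, 4.8e5), function(l)
    threshold_price(tab, lambda = l), numeric(1))
  expect_true(all(diff(prices) > 0))
})

test_that("threshold search reports a missing root or missing QALY gain", {
  expect_error(threshold_price(tab, lambda = 120000, upper = 1e4), "sign change")
  expect_error(threshold_price(null_effect_table(), lambda = 120000),
               "no QALY gain")
})

test_that("model structure options change the result in the expected direction", {
  base <- cua_model(tab)$ce$healthcare$icer_per_qaly
  # multiplicative hazard-ratio application weakens the effect conversion
  mult <- cua_model(tab, cua_options(hr_method = "multiply"))
  expect_false(identical(mult$ce$healthcare$icer_per_qaly, base))
  # exponent-t discounting shrinks all flows by the same first-year factor,
  # leaving the ICER unchanged up to numerical noise
  expt <- cua_model(tab, cua_options(discount_exponent = "t"))
  expect_equal(expt$ce$healthcare$icer_per_qaly, base, tolerance = 1e-9)
  expect_lt(expt$outcomes$healthcare$chemo$cost, cua_model(tab)$outcomes$healthcare$chemo$cost)
  sweep <- structural_sweep(tab)
  expect_identical(nrow(sweep), 16L)
  expect_true(all(is.finite(sweep$icer_per_qaly)))
})
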