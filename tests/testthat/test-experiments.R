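test_that("baseline run starts at zero and grows convex-to-linear", {
  traj <- run_baseline()
  stock <- sd_series(traj, "new drug pricing decision evaluation")
  expect_equal(stock[1], 0)
  expect_true(all(diff(stock) >= 0))
  # flow non-decreasing towards its asymptote => stock increments non-decreasing
  expect_true(all(diff(diff(stock)) >= -1e-12))

  eq <- run_baseline(init_policy = "equilibrium")
  expect_equal(sd_at(eq, "new drug pricing decision evaluation", 50),
               5321.25, tolerance = 1e-9)
})

test_that("halving the integration step leaves the stock trajectory essentially unchanged", {
  m <- japan_pricing_model()
  eq <- stability_test(m, c(1, 0.5, 0.125), init_policy = "equilibrium")
  expect_equal(attr(eq, "reference_dt"), 1)
  expect_equal(eq$max_abs_deviation[eq$dt == 1], 0)
  expect_true(all(eq$max_abs_deviation < 1e-9))

  def <- stability_test(m, c(1, 0.5, 0.125), init_policy = "default")
  expect_equal(def$max_abs_deviation[def$dt == 1], 0)
  expect_true(all(def$rel_deviation_at_end < 0.001))

  solo <- stability_test(m, 1)
  expect_equal(solo$max_abs_deviation, 0)
  expect_equal(solo$max_rel_deviation, 0)
})

test_that("one-at-a-time perturbations shift the flow asymptote as derived by hand", {
  m <- japan_pricing_model()
  nm <- oat_sensitivity(m, "new mechanism score", scale = 1.8)
  expect_equal(nm[[1]]$asymptotic_flow, 119.345, tolerance = 1e-12)
  expect_equal(nm[[2]]$parameter, "(baseline)")
  expect_equal(nm[[2]]$asymptotic_flow, 106.425)

  comb <- oat_sensitivity(m, "combination to enhance effectiveness score", 1.8)
  expect_equal(comb[[1]]$asymptotic_flow, 109.305, tolerance = 1e-12)

  null <- oat_sensitivity(m, "new mechanism score", scale = 1)
  expect_equal(null[[1]]$delta_flow_vs_baseline, 0)
  expect_identical(null[[1]]$trajectory$values, null[[2]]$trajectory$values)

  expect_error(oat_sensitivity(m, "no such knob"), "unknown parameter")
  expect_error(oat_sensitivity(m, "value premium"), "not a constant")
})

test_that("analytic gains match path-coefficient hand sums and flag missing constants", {
  m <- japan_pricing_model()
  expect_equal(analytic_gain(
    m, "additional clinical significance of nhs accreditation score"), 7.2)
  expect_equal(analytic_gain(m, "japan premiere/global synchronisation score"), 4.475)
  expect_equal(analytic_gain(m, "major disease score"), 4.475)
  expect_equal(analytic_gain(m, "new mechanism score"), 8.075)
  expect_equal(analytic_gain(m, "significant improvement in efficacy score"), 6.275)
  expect_equal(analytic_gain(m, "special designation base"), 3.325)
  # the split-base variant no longer carries the shared base constant
  expect_error(analytic_gain(japan_special_premium_model(),
                             "special designation base"),
               "special designation base")
})

test_that("simulated deltas equal analytic gain x (scale - 1) x base for every constant", {
  m <- japan_pricing_model()
  cfg <- sd_config(t_end = 100)
  runs <- oat_sensitivity(m, names(sd_constants(m)), scale = 1.8, config = cfg)
  flow <- "new drug pricing decision variation"
  base_run <- runs[[length(runs)]]
  for (r in runs[-length(runs)]) {
    predicted <- analytic_gain(m, r$parameter) * 0.8 * r$base_value
    expect_equal(r$delta_flow_vs_baseline, predicted, tolerance = 1e-9)
    # late-horizon simulated flow agrees with the perturbed asymptote
    expect_lt(abs(sd_at(r$trajectory, flow, 100) - r$asymptotic_flow) /
                r$asymptotic_flow, 1e-6)
    # monotonicity: upscaling a constant never lowers the stock
    expect_true(all(r$trajectory$values[, "new drug pricing decision evaluation"] >=
                      base_run$trajectory$values[, "new drug pricing decision evaluation"] - 1e-9))
  }
})

test_that("rankings reproduce the SAKIGAKE and special-designation orderings", {
  m <- japan_pricing_model()
  sak_group <- c("new mechanism score", "significant improvement in efficacy score",
                 "japan premiere/global synchronisation score", "major disease score")
  ranking <- rank_parameters(oat_sensitivity(m, sak_group, 1.8))
  expect_equal(ranking$parameter[1], "new mechanism score")
  expect_equal(ranking$parameter[2], "significant improvement in efficacy score")
  expect_equal(ranking$delta_flow_vs_baseline, c(12.92, 10.04, 7.16, 7.16),
               tolerance = 1e-9)
  # exact tie between the last two, reported as a tie in alphabetical order
  expect_equal(ranking$rank, c(1L, 2L, 3L, 3L))
  expect_equal(ranking$parameter[3:4],
               sort(c("japan premiere/global synchronisation score",
                      "major disease score")))

  special <- rank_parameters(oat_sensitivity(
    japan_special_premium_model(),
    c("rare disease base", "children base", "small market base"), 1.8))
  expect_equal(special$parameter,
               c("rare disease base", "children base", "small market base"))
  expect_equal(special$delta_flow_vs_baseline, c(4.6, 4.5, 4.2), tolerance = 1e-9)

  # NHS accreditation dominates the other single-score clinical criteria
  others <- c("serious diseases without standard treatment score",
              "safety better than comparator score", "evidence from rct score",
              "evidence from other score")
  nhs_gain <- analytic_gain(m, "additional clinical significance of nhs accreditation score")
  for (p in others) expect_gt(nhs_gain, analytic_gain(m, p))

  expect_equal(nrow(rank_parameters(structure(list(), class = "sd_sensitivity_runs"))), 0)
})

test_that("sensitivity summaries carry one row per run including the baseline", {
  runs <- oat_sensitivity(japan_pricing_model(),
                          c("new mechanism score", "major disease score"), 1.8)
  s <- sensitivity_summary(runs)
  expect_equal(nrow(s), 3)
  expect_equal(s$parameter[3], "(baseline)")
  expect_equal(s$delta_flow_vs_baseline[3], 0)
})
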