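test_that("discount factor: convention, zero rate, one-year value", {
  expect_equal(discount_factor(1, 0.035), 1)
  expect_equal(discount_factor(37, 0), 1)
  expect_equal(discount_factor(13, 0.035), 1 / 1.035)
  expect_equal(round(discount_factor(13, 0.035), 5), 0.96618)
  expect_error(discount_factor(0, 0.035), class = "oab_input_error")
})

test_that("cycle costs reproduce worked unit-cost arithmetic", {
  params <- cached_default_paramset(1)$params

  # everyone off treatment at incontinence level 5: pads only
  d_off <- make_point_dist(params, "solifenacin_5mg", "off|1|1", 5, 5)
  cc <- cycle_cost(d_off, zero_tally(), params)
  expect_equal(unname(cc["pads"]), 121.30 * 0.17)
  expect_equal(unname(cc["pads"]), 20.621)
  expect_equal(sum(cc[names(cc) != "pads"]), 0)

  # everyone on first-line solifenacin at incontinence level 1, no events
  d_on <- make_point_dist(params, "solifenacin_5mg", "on|1|2|0|0", 3, 1)
  cc <- cycle_cost(d_on, zero_tally(), params)
  expect_equal(unname(cc["drug_acquisition"]), 28.00)
  expect_equal(unname(cc["pads"]), 6.97 * 0.17)
  expect_equal(unname(cc["pads"]), 1.1849)
  expect_equal(unname(cc["other_oab_drugs"]), 0)

  # next-line occupancy is costed as other OAB drugs
  d_nl <- make_point_dist(params, "solifenacin_5mg", "on|2|1|1|0", 3, 1)
  cc <- cycle_cost(d_nl, zero_tally(), params)
  expect_equal(unname(cc["drug_acquisition"]), 0)
  expect_equal(unname(cc["other_oab_drugs"]),
               params$drugs$tolterodine_er_4mg$monthly_cost)

  # visit costing: entry uses the first-visit GP rate, later initiations
  # the follow-up rate, one specialist visit each by default
  tl <- zero_tally(); tl["entry"] <- 1
  cc <- cycle_cost(d_on, tl, params)
  expect_equal(unname(cc["gp_visits"]), 65)
  expect_equal(unname(cc["specialist_visits"]), 94)
  tl <- zero_tally(); tl["initiations"] <- 0.5
  cc <- cycle_cost(d_on, tl, params)
  expect_equal(unname(cc["gp_visits"]), 0.5 * 27)
  expect_equal(unname(cc["specialist_visits"]), 0.5 * 94)

  tl <- zero_tally(); tl["btxa_injections"] <- 0.25
  cc <- cycle_cost(d_on, tl, params)
  expect_equal(unname(cc["btxa"]), 0.25 * 1151.98)
})

test_that("cycle QALYs reproduce worked utility arithmetic", {
  params <- cached_default_paramset(1)$params
  params$utility$base_utility <- 0.80

  d55 <- make_point_dist(params, "solifenacin_5mg", "on|1|2|0|0", 5, 5)
  expect_equal(cycle_qaly(d55, params), 0.80 / 12)
  expect_equal(round(cycle_qaly(d55, params), 5), 0.06667)

  d_ae <- make_point_dist(params, "solifenacin_5mg", "on|1|2|0|1", 5, 5)
  expect_equal(cycle_qaly(d_ae, params), (0.80 - 0.0357) / 12)
  expect_equal(round(cycle_qaly(d_ae, params), 5), 0.06369)

  d11 <- make_point_dist(params, "solifenacin_5mg", "on|1|2|0|0", 1, 1)
  expect_equal(cycle_qaly(d11, params), (0.80 + 0.0632 + 0.0586) / 12)
  expect_equal(round(cycle_qaly(d11, params), 5), 0.07682)

  # the decrement applies only on treatment: off-treatment states carry
  # no AE flag
  d_off <- make_point_dist(params, "solifenacin_5mg", "off|1|1", 5, 5)
  expect_equal(cycle_qaly(d_off, params), 0.80 / 12)
})

test_that("null cost/utility parameters accumulate to zero", {
  params <- make_frozen_paramset(horizon = 12)
  for (nm in names(params$drugs)) params$drugs[[nm]]$monthly_cost <- 0
  params$cost <- cost_spec(pads_per_month = c(0, 0), pad_unit_cost = 0,
                           gp_first_visit = 0, gp_followup = 0,
                           specialist_visit = 0, btxa_injection_cost = 0)
  params$utility <- utility_spec(base_utility = 0, mict_coefs = 0,
                                 incont_coefs = 0, ae_decrement = 0)
  arm <- accumulate(run_cohort(params, "solifenacin_5mg"), params)
  expect_equal(arm$total_cost, 0)
  expect_equal(arm$total_qalys, 0)
  expect_equal(unname(arm$cost_by_category), rep(0, 6))
})

test_that("constant cost stream matches the geometric-series closed form", {
  # frozen dynamics: the per-cycle cost (drug + pads) is constant
  params <- make_frozen_paramset(horizon = 60)
  params$settings$annual_discount_rate <- 0.035
  tr <- run_cohort(params, "solifenacin_5mg")
  c1 <- sum(cycle_cost(tr$cycles[[1]]$dist,
                       zero_tally(), params))
  arm <- accumulate(tr, params)
  entry_cost <- params$cost$gp_first_visit + params$cost$specialist_visit
  expected <- c1 * sum(1.035^(-(0:59) / 12)) + entry_cost
  expect_equal(arm$total_cost, expected, tolerance = 1e-9)

  params$settings$annual_discount_rate <- 0
  arm0 <- accumulate(run_cohort(params, "solifenacin_5mg"), params)
  expect_equal(arm0$total_cost, 60 * c1 + entry_cost, tolerance = 1e-9)
})

test_that("discounting can only reduce totals; categories reconcile", {
  params <- cached_default_paramset(1)$params
  tr <- run_cohort(params, "solifenacin_5mg")
  disc <- accumulate(tr, params)
  p0 <- params; p0$settings$annual_discount_rate <- 0
  undisc <- accumulate(tr, p0)
  expect_lt(disc$total_cost, undisc$total_cost)
  expect_lt(disc$total_qalys, undisc$total_qalys)
  expect_equal(disc$total_cost, sum(disc$cost_by_category))
  expect_lte(disc$total_qalys, 5)
  expect_gte(disc$total_qalys, 0)
})

test_that("comparison classifies dominance, thresholds and equivalence", {
  a <- list(arm = "a", total_cost = 1733, total_qalys = 3.732)
  b <- list(arm = "b", total_cost = 1756, total_qalys = 3.725)
  cea <- compare(a, b, wtp = 30000)
  expect_equal(cea$incremental_cost, -23)
  expect_equal(cea$incremental_qalys, 0.007)
  expect_equal(cea$classification, "dominant")

  cea2 <- compare(a, a)
  expect_equal(cea2$incremental_cost, 0)
  expect_equal(cea2$incremental_qalys, 0)
  expect_true(is.na(cea2$icer))
  expect_equal(cea2$classification, "equivalent")

  c1 <- list(total_cost = 100, total_qalys = 0.01)
  c0 <- list(total_cost = 0, total_qalys = 0)
  cea3 <- compare(c1, c0, wtp = 30000)
  expect_equal(cea3$icer, 10000)
  expect_equal(cea3$classification, "cost_effective_at_wtp")
  cea4 <- compare(list(total_cost = 400, total_qalys = 0.01), c0,
                  wtp = 30000)
  expect_equal(cea4$icer, 40000)
  expect_equal(cea4$classification, "not_cost_effective_at_wtp")
  cea5 <- compare(list(total_cost = 100, total_qalys = -0.01), c0,
                  wtp = 30000)
  expect_equal(cea5$classification, "dominated")
})

test_that("net monetary benefit and classification agree", {
  cea <- compare(list(total_cost = 1733, total_qalys = 3.7316),
                 list(total_cost = 1756, total_qalys = 3.7250))
  expect_equal(net_monetary_benefit(cea, 30000),
               30000 * cea$incremental_qalys + 23)
  expect_equal(round(net_monetary_benefit(cea, 30000), 1), 221.0)
  expect_equal(net_monetary_benefit(cea, 0), -cea$incremental_cost)

  # NMB >= 0 at w <=> dominant or cost-effective at w (dQ > 0 cases)
  cases <- list(c(-50, 0.01), c(50, 0.01), c(400, 0.01), c(290, 0.01))
  for (cs in cases) {
    cea_i <- compare(list(total_cost = cs[1], total_qalys = cs[2]),
                     list(total_cost = 0, total_qalys = 0), wtp = 30000)
    nmb <- net_monetary_benefit(cea_i, 30000)
    in_set <- cea_i$classification %in% c("dominant",
                                          "cost_effective_at_wtp")
    expect_equal(nmb >= 0, in_set)
  }
})

test_that("half-cycle correction shrinks event-free accumulation shifts", {
  params <- make_reduced_paramset(horizon = 12)
  base <- run_cea(params, "tolterodine_er_4mg")
  params$settings$half_cycle_correction <- TRUE
  hcc <- run_cea(params, "tolterodine_er_4mg")
  # still a finite, nearby result; QALY totals move toward the baseline
  # utility level but by less than one cycle's worth
  expect_lt(abs(hcc$intervention$total_qalys -
                base$intervention$total_qalys), 1 / 12)
  expect_equal(hcc$cea$classification, base$cea$classification)
})

test_that("results tabulate in the published layout", {
  params <- make_reduced_paramset(horizon = 12)
  res <- list(
    tolterodine_er_4mg = run_cea(params, "tolterodine_er_4mg"),
    oxybutynin_ir_10mg = run_cea(params, "oxybutynin_ir_10mg"))
  tab <- cea_table(res)
  expect_equal(tab$quantity,
               c("drug_acquisition", "other_oab_drugs", "gp_visits",
                 "specialist_visits", "btxa", "pads", "total_costs",
                 "total_qalys", "incremental_costs",
                 "incremental_qalys", "icer"))
  expect_equal(ncol(tab), 4L)  # quantity + intervention + 2 comparators
})
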