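test_that("stoichiometric factors derive from the starch monomer", {
  f <- stoichiometric_factors()
  # the conventional two-decimal figures truncate the exact ratios
  expect_equal(floor(f$co2_per_dm * 100) / 100, 1.62)
  expect_equal(round(f$c_per_dm, 2), 0.44)
  # independent atomic-weight arithmetic: 6 CO2 per C6H10O5 monomer
  expect_equal(f$co2_per_dm, 264.057 / 162.141, tolerance = 2e-4)
  expect_equal(f$c_per_dm, 72.066 / 162.141, tolerance = 2e-4)
})

test_that("daily NPP follows delta-B plus mortality by definition", {
  # constant biomass, zero mortality: nothing produced
  tr <- make_fake_traj(agb = rep(100, 10), bgb = rep(500, 10))
  npp <- daily_npp(tr)
  expect_true(all(npp$npp_total == 0))
  # steady growth of 5 with mortality 1 gives NPP 6
  tr <- make_fake_traj(agb = 100 + 5 * (1:10), bgb = rep(500, 10),
                       m_above = 1, agb0 = 100)
  npp <- daily_npp(tr)
  expect_true(all(npp$npp_above == 6))
  expect_true(all(npp$npp_below == 0))
  expect_error(daily_npp(make_fake_traj(agb = 1, bgb = 1)), "2 days")
})

test_that("NPP telescopes over the season, with harvest excluded", {
  traj <- baseline_trajectory()
  npp <- daily_npp(traj)
  init <- attr(traj, "initial")
  lhs <- sum(npp$npp_total)
  rhs <- (traj$agb[365] + traj$bgb[365]) - (init$agb + init$bgb) +
    sum(traj$mortality_above + traj$mortality_below) + sum(traj$harvested)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  # the harvest day is not a catastrophic negative-production spike
  h <- baseline_schedule$t_harvest
  expect_gt(npp$npp_total[h], -50)
})

test_that("carbon conversion is linear and sign preserving", {
  expect_equal(npp_to_carbon(10), 4.4)
  expect_equal(npp_to_carbon(numeric(5)), numeric(5))
  expect_equal(npp_to_carbon(-3, 0.5), -1.5)
  x <- rnorm(20)
  expect_equal(npp_to_carbon(3 * x, 0.44), 3 * npp_to_carbon(x, 0.44))
  expect_error(npp_to_carbon(1, 0), "> 0")
})

test_that("calendar aggregation partitions the year", {
  agg <- aggregate_carbon(rep(1, 365))
  expect_equal(unname(agg$monthly[["Jan"]]), 31)
  expect_equal(unname(agg$monthly[["Feb"]]), 28)
  expect_equal(agg$annual, 365)
  x <- rnorm(365)
  agg <- aggregate_carbon(x)
  expect_equal(sum(agg$monthly), agg$annual, tolerance = 1e-12)
  expect_equal(agg$annual, sum(x))
  expect_error(aggregate_carbon(rep(1, 360)), "365")
})

test_that("site stock arithmetic converts per-area carbon to tonnes", {
  expect_equal(total_stock(1000, 1), 10)
  expect_equal(total_stock(123.4, 0), 0)
  expect_error(total_stock(10, -1), ">= 0")
})

test_that("the ledger is internally consistent at every aggregation level", {
  led <- carbon_ledger(baseline_trajectory(), area_ha = hwnr_area_ha())
  # whole plant = above + below at daily, monthly and annual level
  expect_equal(led$daily$carbon_total,
               led$daily$carbon_above + led$daily$carbon_below)
  expect_equal(led$monthly$carbon_total,
               led$monthly$carbon_above + led$monthly$carbon_below)
  expect_equal(led$annual$total, led$annual$above + led$annual$below,
               tolerance = 1e-9)
  expect_equal(sum(led$monthly$carbon_total), led$annual$total,
               tolerance = 1e-9)
  # living + mortality decomposition matches the total
  expect_equal(led$annual$living_above + led$annual$living_below +
                 led$annual$mortality, led$annual$total, tolerance = 1e-9)
  expect_equal(led$total_stock_tc, total_stock(led$annual$total, 86.58))
})

test_that("scaling NPP scales all carbon aggregates linearly", {
  tr <- make_fake_traj(agb = cumsum(runif(365, 0, 5)),
                       bgb = 500 + cumsum(rnorm(365)), m_above = 0.5)
  led1 <- carbon_ledger(tr)
  led2 <- carbon_ledger(tr, c_per_dm = 0.88)
  expect_equal(led2$annual$total, 2 * led1$annual$total, tolerance = 1e-9)
  expect_equal(led2$monthly$carbon_total, 2 * led1$monthly$carbon_total,
               tolerance = 1e-9)
})
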