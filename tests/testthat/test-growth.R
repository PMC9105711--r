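params0 <- reed_params()
sched0 <- baseline_schedule
frc0 <- baseline_forcing

test_that("light profile follows Beer-Lambert over cumulated biomass", {
  # empty canopy: everyone sees the incident radiation
  expect_equal(light_profile(numeric(3), 10, 0.01), rep(10, 3))
  # one layer of biomass b: the layer below sees I0 * exp(-k b)
  prof <- light_profile(c(50, 0), 12, 0.004)
  expect_equal(prof, c(12, 12 * exp(-0.004 * 50)))
  # multi-layer profile equals an explicit cumulative-sum loop oracle
  layers <- c(30, 12, 7, 0.5)   # top -> bottom
  k <- 0.0085
  got <- light_profile(layers, 9.3, k)
  above <- 0
  for (j in seq_along(layers)) {
    expect_equal(got[j], 9.3 * exp(-k * above))
    above <- above + layers[j]
  }
  expect_true(all(diff(got) <= 0))
  expect_error(light_profile(c(1, -2), 10, 0.01), "negative")
})

test_that("layer photosynthesis has the stated limits and scalings", {
  p <- params0
  expect_equal(layer_photosynthesis(0, 10, p$t_opt, p), 0)
  # light saturation at the optimum temperature approaches p_max * biomass
  sat <- layer_photosynthesis(5, 1e9, p$t_opt, p, age = 0)
  expect_equal(sat, p$p_max * 5, tolerance = 1e-6)
  # linear in p_max
  p2 <- reed_params(p_max = 2 * p$p_max)
  expect_equal(layer_photosynthesis(3, 8, 22, p2),
               2 * layer_photosynthesis(3, 8, 22, p))
  # nutrient response: monotone increasing and concave in k_np
  prod_at <- function(k) {
    layer_photosynthesis(3, 8, 22, reed_params(k_np = k))
  }
  expect_true(prod_at(1.5) > prod_at(1))
  expect_true(prod_at(0.5) < prod_at(1))
  expect_true(prod_at(2) < 2 * prod_at(1))
  # age reduces capacity
  expect_true(layer_photosynthesis(3, 8, 22, p, age = 60) <
                layer_photosynthesis(3, 8, 22, p, age = 0))
})

test_that("respiration follows the Q10 law", {
  expect_equal(respiration(0, 25, 0.01, 2), 0)
  expect_equal(respiration(80, 20, 0.01, 2), 0.8)    # reference temperature
  expect_equal(respiration(80, 30, 0.01, 2), 1.6)    # one Q10 doubling
  expect_equal(respiration(80, 10, 0.01, 2), 0.4)
})

test_that("mortality switches to senescent rates at t_s", {
  st <- reed_state(layers = c(12, 12, 6), flower = 5, roots = 40,
                   old_rhizome = 900, new_rhizome = 100)
  pre <- mortality(st, sched0$t_s - 1, sched0, params0)
  post <- mortality(st, sched0$t_s, sched0, params0)
  expect_equal(pre$shoot, params0$m_shoot * 30)
  expect_equal(post$shoot, params0$m_shoot_senescent * 30)
  expect_equal(post$flower, params0$m_flower_senescent * 5)
  expect_equal(pre$old_rhizome, post$old_rhizome)   # below ground unchanged
  zero <- mortality(reed_state(), 100, sched0, params0)
  expect_true(all(unlist(zero) == 0))
})

test_that("translocation redistributes mass and honors the schedule", {
  p <- reed_params(f_up = 0.02)
  st <- reed_state(layers = c(10), old_rhizome = 100)
  # before t_r: nothing moves
  tr <- translocation(st, sched0$t_r - 1, sched0, p, gross_production = 5)
  expect_true(all(tr == 0))
  # in the upward window: f_up * old_rhizomes leaves the old rhizomes
  tr <- translocation(st, 150, sched0, p, gross_production = 0)
  expect_equal(unname(tr["old_rhizome"]), -2)
  expect_equal(unname(tr["roots"]), 2 * p$f_up_root)
  expect_equal(sum(tr), 0, tolerance = 1e-12)
  # conservation holds on arbitrary days and states
  set.seed(11)
  for (i in 1:25) {
    st_i <- reed_state(layers = runif(5, 0, 20), flower = runif(1, 0, 30),
                       roots = runif(1, 0, 200),
                       old_rhizome = runif(1, 0, 2000),
                       new_rhizome = runif(1, 0, 800))
    tr_i <- translocation(st_i, sample(365, 1), sched0, params0,
                          gross_production = runif(1, 0, 60))
    expect_lt(abs(sum(tr_i)), 1e-12)
  }
})

test_that("shoot growth allocation conserves mass and controls height", {
  p <- params0
  # an established canopy with f_elong = 0 never gains height
  p0 <- reed_params(f_elong = 0)
  st <- reed_state(layers = c(p$shoot_density, p$shoot_density / 2))
  add <- elongation(3, st, p0)
  expect_equal(length(add), length(st$layers))
  expect_equal(sum(add), 3)
  # pure elongation of an empty canopy: one layer's worth -> 1 cm
  p1 <- reed_params(f_elong = 1)
  add <- elongation(p$shoot_density, reed_state(), p1)
  expect_equal(sum(add > 0), 1)
  expect_equal(add[1], p$shoot_density)
  # arbitrary sequences conserve the allocated total
  set.seed(4)
  for (i in 1:20) {
    st_i <- reed_state(layers = runif(sample(1:30, 1), 0, 15))
    amt <- runif(1, 0, 80)
    expect_equal(sum(elongation(amt, st_i, p)), amt, tolerance = 1e-10)
  }
})

test_that("budget derivatives satisfy dB/dt = P - R - M + Tr exactly", {
  st <- reed_state(layers = c(12, 12, 8), ages = c(20, 10, 3), flower = 4,
                   roots = 60, old_rhizome = 1200, new_rhizome = 150)
  for (day in c(100, 150, 210, 230, 280)) {
    d <- derivatives(st, day, list(temperature = 22, radiation = 10),
                     params0, sched0)
    lhs <- d$dBdt
    f <- d$fluxes
    rhs <- f$P - f$R - f$M + f$Tr
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  # zero state pre-season: all derivatives vanish
  d0 <- derivatives(reed_state(), 50, list(temperature = 0, radiation = 3),
                    params0, sched0)
  expect_true(all(abs(d0$dBdt) < 1e-12))
})

test_that("one-day RK4 matches the exponential oracle on pure decay", {
  # only old-rhizome respiration active, at the Q10 reference temperature
  p <- reed_params(p_max = 1e-9, r_below = 0.1, r_above = 0, m_shoot = 0,
                   m_root = 0, m_rhizome = 0, f_up = 0, bgb_init = 100)
  st <- reed_state(old_rhizome = 100)
  out <- rk4_step(st, 50, list(temperature = 20, radiation = 0), p, sched0)
  expect_equal(out$state$old_rhizome, 100 * exp(-0.1), tolerance = 1e-6)
  # zero derivatives leave the state unchanged
  pz <- reed_params(p_max = 1e-12, r_above = 0, r_below = 0, m_shoot = 0,
                    m_root = 0, m_rhizome = 0, f_up = 0)
  stz <- reed_state(layers = c(5, 3), old_rhizome = 700)
  outz <- rk4_step(stz, 30, list(temperature = 5, radiation = 0), pz, sched0)
  expect_equal(outz$state$old_rhizome, 700, tolerance = 1e-9)
  expect_equal(sum(outz$state$layers), 8, tolerance = 1e-9)
})

test_that("a one-day step agrees with a composed quarter-step integration", {
  # march the public stepper to midsummer, then compare step sizes
  advance <- function(until, h = 1) {
    st <- reed_state(old_rhizome = params0$bgb_init)
    for (d in seq_len(until)) {
      for (i in seq_len(1 / h)) {
        st <- rk4_step(st, d, frc0[d, ], params0, sched0, h = h)$state
      }
      st$ages <- st$ages + 1
    }
    st
  }
  st180 <- advance(180)
  full <- rk4_step(st180, 181, frc0[181, ], params0, sched0, h = 1)$state
  quarter <- st180
  for (i in 1:4) {
    quarter <- rk4_step(quarter, 181, frc0[181, ], params0, sched0,
                        h = 0.25)$state
  }
  agb <- function(s) sum(s$layers) + s$flower
  expect_equal(agb(full), agb(quarter), tolerance = 1e-3)
})

test_that("a season without photosynthesis never exceeds the mobilized seed", {
  p <- reed_params(p_max = 1e-9)
  traj <- integrate_season(p, sched0, frc0)
  # everything above ground came from upward translocation
  expect_lt(max(traj$agb), sum(traj$translocation_up))
  led <- carbon_ledger(traj)
  expect_lt(led$annual$total, 0)
})

test_that("the baseline season is mass conserving with non-negative pools", {
  traj <- baseline_trajectory()
  expect_lt(mass_balance_residual(traj), 1e-9)
  pools <- c("shoot", "flower", "roots", "old_rhizome", "new_rhizome")
  for (pl in pools) expect_true(all(traj[[pl]] >= 0))
  # harvest empties the canopy
  expect_equal(traj$agb[sched0$t_harvest], 0)
  expect_gt(traj$harvested[sched0$t_harvest], 0)
  # year-end reserves at least replenish the initial stock
  expect_gte(traj$bgb[365], traj$bgb[1])
})

test_that("forcing must cover the full year", {
  expect_error(integrate_season(params0, sched0, frc0[1:100, ]),
               "days 1..365")
  bad <- frc0
  names(bad)[2] <- "temp"
  expect_error(integrate_season(params0, sched0, bad), "columns")
})

test_that("initial below-ground biomass is recovered from observations", {
  p <- params0
  truth <- reed_params(bgb_init = 2200)
  obs <- synth_agb_observations(truth, sched0, frc0)
  fit <- find_initial_bgb(c(1600, 2200, 2800), obs, p, sched0, frc0)
  expect_equal(fit$bgb_init, 2200)
  # single candidate is returned unconditionally
  one <- find_initial_bgb(1500, obs, p, sched0, frc0)
  expect_equal(one$bgb_init, 1500)
  # exact ties resolve to the smaller candidate
  tie <- find_initial_bgb(c(2200, 2200.0), obs, p, sched0, frc0)
  expect_equal(tie$bgb_init, 2200)
  expect_error(find_initial_bgb(numeric(0), obs, p, sched0, frc0),
               "at least one")
})
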