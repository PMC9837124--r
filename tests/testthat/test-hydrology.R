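test_that("profiles classify by the 65% organic matter rule down to 0.3 m", {
  peat <- uniform_column(n = 10, om = 0.70)
  expect_equal(classify_profile(peat)$classification, "peatland_grid")
  mineral <- uniform_column(n = 10, om = 0.60, bd = 1.2)
  expect_equal(classify_profile(mineral)$classification, "non_peatland_grid")
  # peat only in the top 0.2 m: too shallow to count as peatland
  shallow <- soil_column(c(replicate(2, soil_layer(0.1, 0.1, 0.70), simplify = FALSE),
                           replicate(8, soil_layer(0.1, 0.8, 0.50), simplify = FALSE)),
                         landuse = "smallholder", wtdx = 0.5)
  expect_equal(classify_profile(shallow)$classification, "non_peatland_grid")
  expect_equal(classify_profile(peat)$layer_is_peat, rep(TRUE, 10))
  expect_error(soil_column(list()), "empty layer")
})

test_that("reference evapotranspiration behaves physically", {
  # no radiative or aerodynamic demand
  calm <- forcing_day(tair = 25, radiation = 0, rh = 100, wind = 0)
  expect_lt(potential_et(calm, 1), 1e-5)
  # linear in the land-cover coefficient
  day <- forcing_day(tair = 28, radiation = 18, rh = 70, wind = 2)
  expect_equal(potential_et(day, 1.6), 2 * potential_et(day, 0.8))
  # frozen worked reference-ET value for T=25, RH=70, rad=20, wind=2 (mm/d)
  ref <- forcing_day(tair = 25, radiation = 20, rh = 70, wind = 2)
  expect_equal(potential_et(ref, 1) * 1000, 3.9112, tolerance = 0.02)
  expect_error(potential_et(forcing_day(rh = 130), 1), "humidity")
  expect_error(potential_et(day, 0), "pft_coefficient")
})

test_that("a balanced column under zero forcing is a fixed point", {
  col <- uniform_column(n = 10, wtdx = 0.5)
  st <- state_saturated_below(col, 0.5)
  expect_equal(st$wtd, 0.5, tolerance = 1e-9)
  step <- step_day(col, st, forcing_day(precip = 0, radiation = 0, rh = 100, wind = 0))
  expect_equal(step$state$theta, st$theta, tolerance = 1e-12)
  expect_true(all(abs(step$ledger) < 1e-12))
})

test_that("rain with no loss pathways becomes storage (conservation)", {
  col <- uniform_column(n = 10, wtdx = 0.5)
  col$lateral_length <- 1e12    # effectively no lateral exchange
  st <- state_saturated_below(col, 0.5)
  step <- step_day(col, st, forcing_day(precip = 20, radiation = 0, rh = 100, wind = 0))
  expect_equal(unname(step$ledger["delta_storage"]), 0.020, tolerance = 1e-9)
  expect_equal(unname(step$ledger["runoff"]), 0)
  expect_lt(ledger_residual(step$ledger), 1e-6)
})

test_that("negative precipitation is rejected", {
  col <- uniform_column()
  expect_error(step_day(col, initial_state(col), forcing_day(precip = -1)),
               "precipitation")
})

test_that("the flux ledger closes for random states and forcing", {
  set.seed(42)
  col_peat <- uniform_column(n = 10, om = 0.9, bd = 0.1, wtdx = 0.5)
  col_min <- uniform_column(n = 10, om = 0.05, bd = 1.3, wtdx = 2, landuse = "non_peat_other")
  for (i in 1:200) {
    col <- if (i %% 2) col_peat else col_min
    p <- peatfire:::column_params(col)
    st <- initial_state(col)
    st$theta <- runif(10, p$theta_r + 0.01, p$theta_s)
    st$ponded <- runif(1, 0, 0.03)
    f <- forcing_day(precip = rexp(1, 1 / 8), tair = runif(1, 22, 33),
                     radiation = runif(1, 5, 28), rh = runif(1, 40, 100),
                     wind = runif(1, 0.2, 6))
    step <- step_day(col, st, f)
    expect_lt(ledger_residual(step$ledger), 1e-6)
    expect_true(all(step$state$theta <= p$theta_s + 1e-9))
    expect_true(all(step$state$theta >= p$theta_r - 1e-9))
  }
})

test_that("daily stepping converges under sub-step refinement", {
  col <- uniform_column(n = 10, wtdx = 0.5)
  st <- state_saturated_below(col, 0.8)
  f <- forcing_block(30, precip = 8)
  wtd24 <- simulate_column(col, st, f, sub_steps = 24)$daily$wtd
  wtd48 <- simulate_column(col, st, f, sub_steps = 48)$daily$wtd
  wtd1 <- simulate_column(col, st, f, sub_steps = 1)$daily$wtd
  expect_lt(max(abs(wtd24 - wtd48)), 0.005)   # halving dt barely moves WTD
  expect_lt(max(abs(wtd24 - wtd1)), 0.05)     # even 1 sub-step is close
})

test_that("water table diagnosis follows the saturated-stack definition", {
  col <- uniform_column(n = 10)   # 10 x 0.1 m = 1 m
  p <- peatfire:::column_params(col)
  st <- initial_state(col)
  # all layers saturated -> surface water table
  st$theta <- p$theta_s
  expect_equal(diagnose_wtd(col, st), 0)
  # saturated from 0.6 m down, field capacity above -> 0.6
  st <- state_saturated_below(col, 0.6)
  expect_equal(diagnose_wtd(col, st), 0.6, tolerance = 1e-9)
  # no saturation anywhere -> capped at total depth
  st$theta <- rep(p$theta_fc[1], 10)
  st$ponded <- 0
  expect_equal(diagnose_wtd(col, st), col$total_depth)
  # ponded water -> water table at the surface
  st$ponded <- 0.01
  expect_equal(diagnose_wtd(col, st), 0)
  # every layer fully below the diagnosed wtd is saturated
  st <- state_saturated_below(col, 0.35)
  wtd <- diagnose_wtd(col, st)
  tops <- seq(0, 0.9, by = 0.1)
  below <- tops >= wtd - 1e-9
  expect_true(all(st$theta[below] >= 0.999 * p$theta_s[below]))
})

test_that("near-surface moisture is the thickness-weighted litter + top-two mean", {
  col <- uniform_column(n = 5, thickness = 0.03)
  st <- initial_state(col)
  st$litter_theta <- 0.5
  st$theta[] <- 0.5
  expect_equal(near_surface_moisture(col, st), 0.5)
  # litter 0.02 m @ 0.2, layers 0.03 m @ 0.5 and 0.8
  st$litter_theta <- 0.2
  st$theta[1] <- 0.5
  st$theta[2] <- 0.8
  expect_equal(near_surface_moisture(col, st),
               (0.02 * 0.2 + 0.03 * 0.5 + 0.03 * 0.8) / 0.08)
  # convexity: bounded by component extrema for random states
  set.seed(7)
  for (i in 1:50) {
    st$litter_theta <- runif(1, 0, 0.9)
    st$theta[1:2] <- runif(2, 0.1, 0.8)
    v <- c(st$litter_theta, st$theta[1:2])
    m <- near_surface_moisture(col, st)
    expect_gte(m, min(v))
    expect_lte(m, max(v))
  }
  one_layer <- soil_column(list(soil_layer(0.1, 0.1, 0.9)), wtdx = 0.5)
  expect_error(near_surface_moisture(one_layer, initial_state(one_layer)),
               "2 soil layers")
})

test_that("lateral flux follows the head gradient sign convention", {
  col <- uniform_column(n = 10, wtdx = 0.8)     # boundary deeper than wtd
  st <- state_saturated_below(col, 0.4)
  step <- step_day(col, st, forcing_day(precip = 0, radiation = 0, rh = 100, wind = 0))
  expect_gt(unname(step$ledger["lateral"]), 0)  # discharge out
  col$wtdx <- 0.1                                # boundary shallower: recharge
  st <- state_saturated_below(col, 0.4)
  step <- step_day(col, st, forcing_day(precip = 0, radiation = 0, rh = 100, wind = 0))
  expect_lt(unname(step$ledger["lateral"]), 0)
})

test_that("deeper boundary water tables give equal or deeper mean WTD", {
  f <- forcing_block(365, precip = 7)
  means <- vapply(c(0.2, 0.5, 0.8), function(wx) {
    col <- uniform_column(n = 10, wtdx = wx)
    mean(simulate_column(col, state_saturated_below(col, wx), f)$daily$wtd)
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})
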