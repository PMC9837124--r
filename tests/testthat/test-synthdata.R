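test_that("weather generation is seeded, seasonal, and calibrated", {
  tr <- synthetic_truth(seed = 9, years = 2008:2009)
  w1 <- gen_weather(tr, 1)
  w2 <- gen_weather(tr, 1)
  expect_identical(w1, w2)                      # same seed, same series
  expect_false(identical(w1$precip, gen_weather(tr, 2)$precip))
  expect_true(all(w1$precip >= 0))
  expect_true(all(w1$rh >= 0 & w1$rh <= 100))
  # dry windows are drier in expectation
  doy <- as.integer(format(w1$date, "%j"))
  long_dry <- doy >= 166 & doy <= 300
  wet <- !(long_dry | (doy >= 15 & doy <= 59))
  expect_lt(mean(w1$precip[long_dry]), mean(w1$precip[wet]))
})

test_that("a unit drought multiplier leaves drought years undisturbed", {
  tr1 <- synthetic_truth(seed = 9, years = 2008:2009,
                         drought_years = 2009L, drought_multiplier = 1)
  tr0 <- synthetic_truth(seed = 9, years = 2008:2009,
                         drought_years = integer(0))
  expect_equal(gen_weather(tr1, 1)$precip, gen_weather(tr0, 1)$precip)
  trd <- synthetic_truth(seed = 9, years = 2008:2009, drought_years = 2009L,
                         drought_multiplier = 0.6)
  wd <- gen_weather(trd, 1)
  yr <- format(wd$date, "%Y")
  w0 <- gen_weather(tr0, 1)
  expect_equal(sum(wd$precip[yr == "2009"]), 0.6 * sum(w0$precip[yr == "2009"]))
})

test_that("long-run annual rainfall matches the configured total within 5%", {
  tr <- synthetic_truth(seed = 2, years = 1901:2000, drought_years = integer(0))
  w <- gen_weather(tr, 1)
  annual <- tapply(w$precip, format(w$date, "%Y"), sum)
  expect_equal(unname(mean(annual)), tr$annual_precip_mm, tolerance = 0.05)
})

test_that("generated grids honour the requested mixture and classify consistently", {
  tr <- synthetic_truth(seed = 5)
  cells <- gen_grid(tr, 50)
  cls <- vapply(cells, `[[`, character(1), "classification")
  expect_equal(sum(cls == "peatland_grid"), 30)     # 60% of 50
  for (cell in cells) {
    expect_equal(classify_profile(cell$column)$classification, cell$classification)
    expect_length(cell$column$layers, 15)
    expect_equal(cell$column$total_depth, 2, tolerance = 1e-9)
  }
  lus <- table(vapply(cells, `[[`, character(1), "landuse"))
  expect_equal(as.vector(lus[c("pristine_forest", "degraded_forest",
                               "industrial_plantation", "smallholder")]),
               c(9, 6, 9, 6))
  expect_identical(gen_grid(tr, 50), cells)          # seeded determinism
  expect_error(gen_grid(tr, 0), "n_cells")
})

test_that("fire rates follow the water-table sigmoid with dryness modifier", {
  tr <- synthetic_truth(seed = 1)
  # saturated column: essentially no expected fires
  expect_lt(fire_rate(tr, 0, 0.3), 0.01 * tr$lambda_max)
  # deep water table, dry surface: rate approaches the maximum
  expect_gt(fire_rate(tr, 1.5, 0.1), 0.99 * tr$lambda_max)
  # wet surface halves the rate under default dryness weight
  expect_equal(fire_rate(tr, 1.5, 0.9), 0.5 * fire_rate(tr, 1.5, 0.1),
               tolerance = 0.02)
  counts <- gen_fire_counts(tr, rep(0, 1000), rep(0.5, 1000))
  expect_true(all(counts == 0))
  expect_identical(gen_fire_counts(tr, c(0.5, 0.6), c(0.3, 0.3)),
                   gen_fire_counts(tr, c(0.5, 0.6), c(0.3, 0.3)))
})

test_that("empirical event frequency traces the sigmoid", {
  tr <- synthetic_truth(seed = 8)
  set.seed(1)
  wtd <- runif(10000, 0, 1)
  counts <- gen_fire_counts(tr, wtd, rep(0.2, 10000))
  lam <- fire_rate(tr, wtd, rep(0.2, 10000))
  # binned observed event frequency vs expected 1 - exp(-lambda)
  bins <- cut(wtd, seq(0, 1, 0.1))
  obs_f <- tapply(counts > 0, bins, mean)
  exp_f <- tapply(1 - exp(-lam), bins, mean)
  n_b <- tapply(counts, bins, length)
  se <- sqrt(exp_f * (1 - exp_f) / n_b)
  expect_true(all(abs(obs_f - exp_f) < 4 * pmax(se, 1e-3)))
})

test_that("observed-moisture synthesis is clamped, seeded noise", {
  theta <- seq(0.05, 0.95, length.out = 200)
  expect_identical(gen_obs_moisture(theta, 0), theta)
  obs <- gen_obs_moisture(theta, 0.3, seed = 4)
  expect_true(all(obs >= 0 & obs <= 1))
  expect_identical(obs, gen_obs_moisture(theta, 0.3, seed = 4))
  expect_error(gen_obs_moisture(theta, -1), "sigma")
})

test_that("generator calls do not disturb the global RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(gen_weather(synthetic_truth(seed = 1, years = 2008L), 1))
  b <- runif(1)
  expect_identical(a, b)
})
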