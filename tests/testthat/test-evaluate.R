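test_that("pooled counts sum subsets that add to the grand total", {
  # 2 peat cells with counts 3 and 4 at one step
  p <- pool_counts(pred = c(1, 1, 1), obs = c(3, 4, 5),
                   cell_id = c("a", "b", "c"), fortnight = c(1, 1, 1),
                   is_peat = c(TRUE, TRUE, FALSE))
  expect_equal(p$peat$obs, 7)
  expect_equal(p$non_peat$obs, 5)
  expect_equal(p$all$obs, 12)
  expect_warning(pool_counts(c(1, 2), c(1, 2), c("a", "b"), c(1, 1),
                             c(TRUE, TRUE)), "empty subset")
  expect_error(pool_counts(1:3, 1:2, c("a", "b"), c(1, 1), c(TRUE, TRUE)),
               "misaligned")
})

test_that("pooled counts match a brute-force group sum on random tables", {
  set.seed(21)
  for (i in 1:20) {
    n <- 200
    cell <- sample(letters[1:8], n, TRUE)
    fn <- sample(1:10, n, TRUE)
    peat_cells <- letters[1:4]
    pred <- rpois(n, 2); obs <- rpois(n, 2)
    p <- pool_counts(pred, obs, cell, fn, cell %in% peat_cells)
    for (f in unique(fn)) {
      k <- fn == f & cell %in% peat_cells
      expect_equal(p$peat$obs[p$peat$fortnight == f], sum(obs[k]))
      expect_equal(p$all$pred[p$all$fortnight == f], sum(pred[fn == f]))
    }
    # conservation: peat + non-peat = all, each fortnight
    m <- merge(p$peat, p$non_peat, by = "fortnight", all = TRUE)
    m[is.na(m)] <- 0
    expect_equal(m$obs.x + m$obs.y, p$all$obs)
  }
})

test_that("r2 and mae match their defining formulas", {
  expect_equal(r2(c(1, 2, 3), c(1, 2, 3)), 1)
  obs <- c(2, 4, 9)
  expect_equal(r2(rep(mean(obs), 3), obs), 0)
  expect_equal(r2(c(1, 2, 4), c(1, 2, 3)), 0.5)   # 1 - 1/2
  expect_error(r2(c(1, 2, 3), c(2, 2, 2)), "zero variance")
  expect_error(r2(1:3, 1:4), "lengths differ")
  expect_equal(mae(c(1, 2), c(2, 4)), 1.5)
  expect_equal(mae(1:5, 1:5), 0)
  expect_equal(mae(3 * c(1, 2), 3 * c(2, 4)), 3 * 1.5)  # homogeneity
})

test_that("metrics agree with brute-force evaluation on random draws", {
  set.seed(33)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    pred <- rnorm(n, 5, 3); obs <- rnorm(n, 5, 3)
    expect_equal(r2(pred, obs), 1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2))
    expect_equal(mae(pred, obs), sum(abs(pred - obs)) / n)
    d <- time_difference(obs)
    expect_equal(d, obs[-1] - obs[-n])
    expect_equal(sum(d), obs[n] - obs[1])   # telescoping
  }
})

test_that("time differencing follows its definition", {
  expect_equal(time_difference(c(5, 3, 9)), c(-2, 6))
  expect_equal(time_difference(rep(4, 6)), rep(0, 5))
  expect_error(time_difference(5), "length >= 2")
})

test_that("the water-table fire threshold is recovered when separable", {
  wtd <- c(seq(0.1, 0.39, by = 0.01), seq(0.41, 0.8, by = 0.01))
  event <- wtd >= 0.40
  est <- estimate_wtd_threshold(wtd, event)
  expect_equal(est$threshold, 0.40)
  expect_equal(est$J, 1)
  expect_true(est$informative)
  expect_error(estimate_wtd_threshold(wtd, rep(TRUE, length(wtd))), "both")
})

test_that("labels independent of the water table are flagged uninformative", {
  set.seed(3)
  wtd <- runif(4000, 0, 1)
  event <- runif(4000) < 0.4
  est <- estimate_wtd_threshold(wtd, event)
  expect_lt(est$J, 0.06)
  expect_false(est$informative)
})

test_that("the threshold estimator is invariant to monotone transforms", {
  set.seed(4)
  wtd <- runif(500, 0, 1)
  event <- runif(500) < plogis((wtd - 0.4) / 0.05)
  base <- estimate_wtd_threshold(wtd, event)
  g <- function(x) x^3            # strictly increasing on [0, 1]
  trans <- estimate_wtd_threshold(g(wtd), event, candidates = g(seq(0, 1, 0.01)))
  expect_equal(g(base$threshold), trans$threshold)
  expect_equal(base$J, trans$J)
})

test_that("daily correlations and subset medians behave", {
  set.seed(6)
  n_days <- 60
  cells <- sprintf("c%02d", 1:6)
  cell_id <- rep(cells, each = n_days)
  modelled <- rnorm(length(cell_id), 0.5, 0.1)
  is_peat <- cell_id %in% cells[1:3]
  r_same <- daily_correlation(modelled, modelled, cell_id, is_peat)
  expect_true(all(abs(r_same$per_cell$r - 1) < 1e-12))
  expect_equal(unname(r_same$medians["all"]), 1)
  centered <- modelled - ave(modelled, cell_id)
  r_anti <- daily_correlation(centered, -centered, cell_id, is_peat)
  expect_true(all(abs(r_anti$per_cell$r + 1) < 1e-12))
  expect_error(daily_correlation(modelled[1:29], modelled[1:29],
                                 rep("x", 29), rep(TRUE, 29)), "30")
  const <- modelled
  const[cell_id == cells[1]] <- 0.5
  expect_warning(daily_correlation(const, modelled, cell_id, is_peat),
                 "constant series")
})

test_that("noise equal to signal attenuates correlation toward 1/sqrt(2)", {
  set.seed(12)
  n_days <- 400; n_cells <- 50
  rs <- vapply(1:n_cells, function(i) {
    sig <- 0.5 + 0.15 * sin(2 * pi * (1:n_days) / 180) + rnorm(n_days, 0, 0.02)
    obs <- sig + rnorm(n_days, 0, sd(sig))
    cor(sig, obs)
  }, numeric(1))
  expect_equal(median(rs), 1 / sqrt(2), tolerance = 0.03)
})
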