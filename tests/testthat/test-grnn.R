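test_that("degenerate and symmetric models predict as the kernel dictates", {
  # single training point: weights normalize to 1 everywhere
  one <- suppressWarnings(
    fit_grnn(matrix(c(2, 3, 4), 1, 3), 40, sigma = 0.3))
  expect_equal(predict(one, matrix(c(0, 0, 0), 1, 3)), 40)
  expect_equal(predict(one, matrix(c(9, 9, 9), 1, 3)), 40)

  # two 1-D points at the ends of the normalized range
  x <- matrix(c(0, 1), ncol = 1, dimnames = list(NULL, "dose"))
  for (s in c(0.1, 0.5, 2)) {
    two <- fit_grnn(x, c(0, 100), sigma = s)
    expect_equal(predict(two, matrix(0.5)), 50)
  }
  # at the y = 0 point with sigma 0.5: weights 1 and exp(-2)
  two <- fit_grnn(x, c(0, 100), sigma = 0.5)
  expect_equal(predict(two, matrix(0)), 100 * exp(-2) / (1 + exp(-2)),
               tolerance = 1e-10)
  expect_equal(predict(two, matrix(0)), 11.92029, tolerance = 1e-6)
})

test_that("predictions are convex combinations of the training targets", {
  set.seed(401)
  for (rep in 1:20) {
    inst <- random_grnn_instance(n = sample(5:40, 1))
    model <- fit_grnn(inst$x, inst$y, sigma = runif(1, 0.01, 3))
    q <- matrix(runif(30, -5, 15), 10, 3)
    p <- predict(model, q)
    expect_true(all(p >= min(inst$y) - 1e-9))
    expect_true(all(p <= max(inst$y) + 1e-9))
  }
})

test_that("spread limits give interpolation and global smoothing", {
  obs <- expand_replicates(disinfection_trial())
  x <- obs[, c("naocl", "h2o2", "time")]
  # unique coordinates: collapse to treatment means first
  trial <- disinfection_trial()
  xm <- trial[, c("naocl", "h2o2", "time")]
  tiny <- fit_grnn(xm, trial$mean, sigma = 1e-4)
  expect_equal(predict(tiny, xm), trial$mean, tolerance = 1e-8)
  # with co-located replicates the sigma -> 0 limit is the local mean
  tiny_rep <- fit_grnn(x, obs$contamination, sigma = 1e-4)
  expect_equal(predict(tiny_rep, xm), trial$mean,
               tolerance = 0.05 + 1e-8)
  huge <- fit_grnn(x, obs$contamination, sigma = 1e6)
  q <- data.frame(naocl = c(0, 7.5, 15), h2o2 = c(30, 1, 0),
                  time = c(1, 18, 3))
  expect_equal(predict(huge, q), rep(mean(obs$contamination), 3),
               tolerance = 1e-3)
})

test_that("predictions are invariant to training-point order", {
  obs <- expand_replicates(disinfection_trial())
  x <- as.matrix(obs[, c("naocl", "h2o2", "time")])
  set.seed(402)
  perm <- sample(nrow(x))
  a <- fit_grnn(x, obs$contamination, sigma = 0.2)
  b <- fit_grnn(x[perm, ], obs$contamination[perm], sigma = 0.2)
  q <- matrix(runif(60, 0, 20), 20, 3)
  expect_equal(predict(a, q), predict(b, q), tolerance = 1e-12)
})

test_that("vectorized prediction matches the two-loop oracle", {
  set.seed(403)
  for (rep in 1:10) {
    inst <- random_grnn_instance(n = 25)
    sigma <- runif(1, 0.05, 1.5)
    model <- fit_grnn(inst$x, inst$y, sigma = sigma)
    q <- matrix(runif(24, 0, 10), 8, 3)
    expect_equal(
      predict(model, q),
      oracle_grnn_predict(inst$x, inst$y, q, sigma,
                          model$scaler$lo, model$scaler$range),
      tolerance = 1e-10)
  }
})

test_that("leave-one-out spread selection matches the brute-force oracle", {
  expect_equal(select_sigma(matrix(1:10, ncol = 1), runif(10, 0, 100),
                            sigma_grid = 0.7), 0.7)

  obs <- expand_replicates(disinfection_trial())
  x <- as.matrix(obs[, c("naocl", "h2o2", "time")])
  y <- obs$contamination
  grid <- default_sigma_grid()
  fast <- loo_rmse(x, y, grid)
  slow <- vapply(grid[c(1, 8, 15, 22, 30)],
                 function(s) oracle_loo_rmse(x, y, s), 1.0)
  expect_equal(fast[c(1, 8, 15, 22, 30)], slow, tolerance = 1e-10)
  chosen <- select_sigma(x, y, grid)
  expect_equal(chosen, grid[which.min(fast)])
  # the selected spread beats the worst candidate by construction
  expect_lt(min(fast), max(fast))

  # ties break toward the smoother (larger) spread
  expect_equal(select_sigma(x, y, c(0.2, 0.2)), 0.2)
  lin_x <- matrix(seq(0, 10, length.out = 20), ncol = 1)
  lin_y <- seq(0, 100, length.out = 20)
  err <- loo_rmse(lin_x, lin_y, grid)
  expect_equal(select_sigma(lin_x, lin_y, grid),
               max(grid[err <= min(err)]))
})

test_that("degenerate features warn and map to a constant", {
  x <- cbind(naocl = c(1, 2, 3, 4), h2o2 = 0, time = c(2, 4, 6, 8))
  expect_warning(model <- fit_grnn(x, c(10, 20, 30, 40), sigma = 0.3),
                 "h2o2")
  p <- suppressWarnings(predict(model, x))
  expect_true(all(is.finite(p)))
})

test_that("serialized models reload with identical predictions", {
  obs <- expand_replicates(disinfection_trial())
  model <- fit_grnn(obs[, c("naocl", "h2o2", "time")], obs$contamination,
                    sigma = 0.25)
  path <- tempfile(fileext = ".json")
  grnn_save(model, path)
  back <- grnn_load(path)
  expect_equal(back$sigma, model$sigma)
  q <- data.frame(naocl = c(3, 12), h2o2 = c(5, 0), time = c(7, 16))
  expect_equal(predict(back, q), predict(model, q), tolerance = 1e-12)
  unlink(path)
})

test_that("invalid spreads, grids and targets are rejected", {
  x <- matrix(runif(30), 10, 3)
  y <- runif(10, 0, 100)
  expect_error(fit_grnn(x, y, sigma = -1), "positive")
  expect_error(select_sigma(x, y, numeric(0)), "empty")
  expect_error(select_sigma(x, y, c(0.1, -0.5)), "positive")
  expect_error(fit_grnn(x, c(y[-10], 150)), "\\[0, 100\\]")
  expect_error(fit_grnn(x, y[-1]), "matching")
})
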