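test_that("the surface follows first-order kill kinetics", {
  p <- surface_params()
  # zero dose leaves the baseline untouched at any immersion time
  expect_equal(contamination_probability(
    data.frame(naocl = 0, h2o2 = 0, time = c(0, 5, 20)), p),
    rep(1, 3))
  # closed form: alpha 0.1, 5 % NaOCl, 10 min -> exp(-5)
  strong <- surface_params(potency_naocl = 0.1, potency_h2o2 = 0)
  expect_equal(contamination_probability(c(5, 0, 10), strong), exp(-5),
               tolerance = 1e-12)
  # exponential limit: huge exposure kills everything
  expect_lt(contamination_probability(c(15, 30, 1e4), p), 1e-12)
})

test_that("the surface is non-increasing in every coordinate", {
  p <- surface_params()
  set.seed(701)
  base <- data.frame(naocl = runif(50, 0, 15), h2o2 = runif(50, 0, 30),
                     time = runif(50, 0, 20))
  p0 <- contamination_probability(base, p)
  for (col in c("naocl", "h2o2", "time")) {
    up <- base
    up[[col]] <- up[[col]] + runif(50, 0.1, 5)
    expect_true(all(contamination_probability(up, p) <= p0 + 1e-12))
  }
})

test_that("simulated replicates have binomial structure on the 20 % grid", {
  certain <- simulate_experiment(params = surface_params(baseline = 1,
                                                         potency_naocl = 0,
                                                         potency_h2o2 = 0),
                                 seed = 3)
  expect_true(all(certain$replicates$contamination == 100))
  sterile <- simulate_experiment(params = surface_params(baseline = 0),
                                 seed = 3)
  expect_true(all(sterile$replicates$contamination == 0))

  sim <- simulate_experiment(seed = 4)
  expect_true(all(sim$replicates$contamination %% 20 == 0))
  expect_identical(sim$replicates,
                   simulate_experiment(seed = 4)$replicates)

  # p = 0.5 with many replicates: mean contamination within 50 +/- 1 %
  half <- simulate_experiment(
    design = data.frame(naocl = 0, h2o2 = 0, time = 5),
    params = surface_params(baseline = 0.5, potency_naocl = 0,
                            potency_h2o2 = 0),
    n_reps = 1e4, seed = 5)
  expect_lt(abs(mean(half$replicates$contamination) - 50), 1)
})

test_that("simulated summaries agree with the reconstruction conventions", {
  sim <- simulate_experiment(seed = 8)
  for (i in seq_len(nrow(sim$summary))) {
    truth <- sort(sim$replicates$contamination[
      sim$replicates$naocl == sim$summary$naocl[i] &
        sim$replicates$h2o2 == sim$summary$h2o2[i] &
        sim$replicates$time == sim$summary$time[i]])
    cand <- oracle_reconstruct(sim$summary$mean[i], sim$summary$se[i])
    expect_false(is.null(cand))
    # the true multiset is always among the printed pair's solutions
    expect_true(any(apply(cand, 1, identical, truth)))
    # and where the pair is unambiguous, reconstruction returns exactly it
    if (nrow(cand) == 1L) {
      expect_equal(reconstruct_replicates(sim$summary$mean[i],
                                          sim$summary$se[i]), truth)
    }
  }
})

test_that("fitted models inherit the surface's monotonicity", {
  for (seed in 1:5) {
    sim <- simulate_experiment(seed = seed)
    model <- fit_grnn(sim$replicates[, c("naocl", "h2o2", "time")],
                      sim$replicates$contamination)
    p_hi <- predict(model, c(15, 0, 15))
    p_lo <- predict(model, c(0, 0, 0))
    expect_lte(p_hi, p_lo)
  }
})

test_that("a noiseless fine grid is learned with high fidelity", {
  grid <- expand.grid(naocl = seq(0, 15, length.out = 8),
                      h2o2 = seq(0, 30, length.out = 8),
                      time = seq(0, 20, length.out = 8))
  y <- 100 * contamination_probability(grid, surface_params())
  set.seed(702)
  hold <- sample(nrow(grid), 100)
  model <- fit_grnn(grid[-hold, ], y[-hold])
  expect_gte(r_squared(y[hold], predict(model, grid[hold, ])), 0.95)
})

test_that("the GA recovers the envelope optimum of a monotone surface", {
  chk <- recover_optimum_check(seed = 1)
  expect_true(chk$pass)
  expect_lte(chk$true_probability, chk$envelope_min + 0.02)
  # NaOCl drives the optimum; its dose is substantial at the optimum
  expect_gt(chk$best[["naocl"]], 0)

  flat <- recover_optimum_check(params = surface_params(baseline = 0),
                                seed = 2)
  expect_true(flat$pass)
  expect_lt(flat$predicted_contamination, 1)
})
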