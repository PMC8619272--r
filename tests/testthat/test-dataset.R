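test_that("packaged trial carries the published summaries", {
  trial <- disinfection_trial()
  expect_equal(nrow(trial), 19L)
  expect_equal(attr(trial, "n_reps"), 3L)
  expect_equal(attr(trial, "seeds_per_rep"), 5L)
  control <- trial[trial$naocl == 0 & trial$h2o2 == 0 & trial$time == 0, ]
  expect_equal(control$mean, 100.0)
  expect_equal(control$se, 0.00)
  best <- trial[trial$naocl == 5 & trial$h2o2 == 0 & trial$time == 15, ]
  expect_equal(best$mean, 0.0)
  expect_equal(best$se, 0.00)
  expect_equal(trial$se[trial$naocl == 5 & trial$time == 5], 17.64)
  expect_equal(trial$se[trial$h2o2 == 30 & trial$time == 10], 11.55)
  expect_false(anyDuplicated(trial[, c("naocl", "h2o2", "time")]) > 0)
})

test_that("reconstruction returns the frozen replicate multisets", {
  expect_equal(reconstruct_replicates(100.0, 0.00), c(100, 100, 100))
  expect_equal(reconstruct_replicates(53.3, 17.64), c(20, 60, 80))
  expect_equal(reconstruct_replicates(80.0, 11.55), c(60, 80, 100))
  expect_equal(reconstruct_replicates(6.7, 6.67), c(0, 0, 20))
})

test_that("reconstruction inverts every trial row uniquely and exactly", {
  trial <- disinfection_trial()
  for (i in seq_len(nrow(trial))) {
    oracle <- oracle_reconstruct(trial$mean[i], trial$se[i])
    expect_equal(nrow(oracle), 1L,
                 info = sprintf("row %d should be unambiguous", i))
    reps <- reconstruct_replicates(trial$mean[i], trial$se[i])
    expect_equal(reps, as.numeric(oracle[1L, ]))
    expect_equal(round(mean(reps), 1), trial$mean[i])
    expect_equal(round(sd(reps) / sqrt(3), 2), trial$se[i])
  }
})

test_that("impossible and ambiguous printed pairs raise typed errors", {
  # 50 is not a multiple of 20, so SE 0 (all replicates equal) is impossible
  expect_error(reconstruct_replicates(50.0, 0.00),
               class = "disinfectr_no_solution")
  # two multisets share this printed pair: {0,60,60} and {20,20,80}
  err <- tryCatch(reconstruct_replicates(40.0, 20.00), error = identity)
  expect_s3_class(err, "disinfectr_ambiguous")
  expect_equal(nrow(err$candidates), 2L)
  expect_true(any(apply(err$candidates, 1, identical, c(0, 60, 60))))
  expect_true(any(apply(err$candidates, 1, identical, c(20, 20, 80))))
})

test_that("expanding the trial yields 57 observations that round-trip", {
  obs <- expand_replicates(disinfection_trial())
  expect_equal(nrow(obs), 57L)
  control <- obs[obs$naocl == 0 & obs$h2o2 == 0 & obs$time == 0, ]
  expect_equal(control$contamination, c(100, 100, 100))
  agg <- aggregate(contamination ~ naocl + h2o2 + time, obs,
                   function(v) c(m = round(mean(v), 1),
                                 s = round(sd(v) / sqrt(3), 2)))
  trial <- disinfection_trial()
  key <- function(d) paste(d$naocl, d$h2o2, d$time)
  idx <- match(key(trial), key(agg))
  expect_equal(agg$contamination[idx, "m"], trial$mean,
               ignore_attr = TRUE)
  expect_equal(agg$contamination[idx, "s"], trial$se,
               ignore_attr = TRUE)
})

test_that("expansion names the offending treatment on failure", {
  bad <- disinfection_trial()
  bad$mean[3] <- 50.0
  bad$se[3] <- 0.00
  expect_error(expand_replicates(bad), "naocl=0.*h2o2=10.*time=10")
})

test_that("stratified split is a deterministic exhaustive partition", {
  obs <- expand_replicates(disinfection_trial())
  key <- function(d) paste(d$naocl, d$h2o2, d$time, d$rep)
  for (seed in c(1, 7, 23, 99, 12345)) {
    sp <- split_replicates(obs, 0.2, seed = seed)
    expect_equal(nrow(sp$train) + nrow(sp$test), 57L)
    expect_length(intersect(key(sp$train), key(sp$test)), 0L)
    expect_setequal(c(key(sp$train), key(sp$test)), key(obs))
    expect_equal(nrow(sp$test), round(57 * 0.2))
    # every treatment keeps at least one replicate in training
    expect_setequal(unique(paste(sp$train$naocl, sp$train$h2o2,
                                 sp$train$time)),
                    unique(paste(obs$naocl, obs$h2o2, obs$time)))
  }
  expect_identical(split_replicates(obs, 0.2, seed = 42),
                   split_replicates(obs, 0.2, seed = 42))
})

test_that("degenerate split fractions are rejected", {
  obs <- expand_replicates(disinfection_trial())
  expect_error(split_replicates(obs, 0), "between 0 and 1")
  expect_error(split_replicates(obs, 1), "between 0 and 1")
  # 99 % holdout would empty treatments from training
  expect_error(split_replicates(obs, 0.99), "empty some treatments")
})

test_that("experiment CSV round-trips and reports schema violations", {
  trial <- disinfection_trial()
  path <- tempfile(fileext = ".csv")
  write_experiment_csv(trial, path)
  back <- read_experiment_csv(path)
  expect_equal(back, trial, ignore_attr = TRUE)

  broken <- trial[, c("naocl", "h2o2", "time", "mean")]
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(broken, p2, row.names = FALSE)
  expect_error(read_experiment_csv(p2), "se")

  neg <- trial
  neg$naocl[4] <- -1
  p3 <- tempfile(fileext = ".csv")
  utils::write.csv(neg, p3, row.names = FALSE)
  expect_error(read_experiment_csv(p3), "row\\(s\\) 4")

  dup <- trial
  dup[2, c("naocl", "h2o2", "time")] <- dup[1, c("naocl", "h2o2", "time")]
  p4 <- tempfile(fileext = ".csv")
  utils::write.csv(dup, p4, row.names = FALSE)
  expect_error(read_experiment_csv(p4), "duplicate")
  unlink(c(path, p2, p3, p4))
})
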