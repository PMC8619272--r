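#!/usr/bin/env Rscript
# Stage 2: fit the Gaussian-kernel contamination model and evaluate it
# over seeded stratified holdouts.
#
# The original study reports R^2 0.938 (train) / 0.918 (test) from a
# single, unreported split with an unreported spread. Neither is
# recoverable, so this run reports the seed-median picture instead:
# 10 stratified 80/20 splits derived from one master seed, spread chosen
# per split by leave-one-out RMSE. It also quantifies the replicate-noise
# ceiling - the best R^2 any model could reach against held-out
# observations discretized to multiples of 20 % - and the mean-level
# (19-point) variant for comparison.

library(disinfectr)

dir.create("results", showWarnings = FALSE)
master <- 1L

obs <- expand_replicates(disinfection_trial())
fit <- headline_fit(obs, n_seeds = 10, seed = master)
write.csv(fit$per_seed, "results/model_performance.csv", row.names = FALSE)

med <- apply(fit$per_seed[, -1], 2, median)
cat(sprintf("Replicate-level model (57 obs), master seed %d:\n", master))
cat(sprintf("  median sigma (LOO):        %.3f\n", med["sigma"]))
cat(sprintf("  median train R2/RMSE/MBE:  %.3f / %.3f / %.3f\n",
            med["train_r2"], med["train_rmse"], med["train_mbe"]))
cat(sprintf("  median test  R2/RMSE/MBE:  %.3f / %.3f / %.3f\n",
            med["test_r2"], med["test_rmse"], med["test_mbe"]))
cat(sprintf("  headline median min(train R2, test R2): %.3f\n", fit$headline))

# ceiling: predict every observation by its treatment's true mean
sst <- sum((obs$contamination - mean(obs$contamination))^2)
ssw <- sum(unlist(lapply(
  split(obs$contamination, paste(obs$naocl, obs$h2o2, obs$time)),
  function(v) sum((v - mean(v))^2))))
cat(sprintf(
  "  replicate-noise R2 ceiling (treatment-mean predictor): %.3f\n",
  1 - ssw / sst))
cat("  (test R2 against 5-seed replicates is noise-limited: outcomes are\n")
cat("   multiples of 20 %, so holdout R2 cannot stably exceed ~0.94.)\n\n")

means <- data.frame(disinfection_trial()[, c("naocl", "h2o2", "time")],
                    contamination = disinfection_trial()$mean)
fit_m <- headline_fit(means, n_seeds = 10, seed = master)
cat(sprintf("Mean-level model (19 obs): headline %.3f, median test R2 %.3f\n",
            fit_m$headline, median(fit_m$per_seed$test_r2)))

model <- fit_grnn(obs[, c("naocl", "h2o2", "time")], obs$contamination)
grnn_save(model, "results/grnn_model.json")
cat(sprintf("\nFull-data model: sigma %.4f, saved to results/grnn_model.json\n",
            model$sigma))
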