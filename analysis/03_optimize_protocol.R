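#!/usr/bin/env Rscript
# Stage 3: minimize predicted contamination over protocol space.
#
# The genetic algorithm (population 200, 1000 generations, roulette
# selection, two-point crossover at fraction 0.6, uniform mutation 0.05)
# searches the experimental envelope - NaOCl 0-15 %, H2O2 0-30 %,
# immersion 0-20 min - for the protocol minimizing the fitted model's
# predicted contamination. The fitted surface has a broad plateau of
# near-zero predictions over high-hypochlorite/long-immersion protocols,
# so the optimum's coordinates vary with the seed while its predicted
# contamination stays at 0 % (rounded).

library(disinfectr)

dir.create("results", showWarnings = FALSE)
master <- 1L

obs <- expand_replicates(disinfection_trial())
model <- fit_grnn(obs[, c("naocl", "h2o2", "time")], obs$contamination)

result <- run_ga(function(m) predict(model, m),
                 ga_config(seed = derive_seed(master, 500L)))
print(result)
cat(sprintf("Predicted contamination at optimum rounds to %d %%\n",
            round(result$best_objective)))

write.csv(result$history, "results/ga_trace.csv", row.names = FALSE)
jsonlite::write_json(
  list(protocol = as.list(round(result$best, 3)),
       predicted_contamination = result$best_objective,
       predicted_contamination_rounded = round(result$best_objective),
       sigma = model$sigma, seed = result$seed),
  "results/optimal_protocol.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("Wrote results/optimal_protocol.json and results/ga_trace.csv\n")
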