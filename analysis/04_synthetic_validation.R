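#!/usr/bin/env Rscript
# Stage 4: validate the whole pipeline against a known ground truth.
#
# The real experiment has no withheld truth to test the optimizer
# against, so this stage simulates one: a first-order kill-kinetics
# surface (hypochlorite ~25x as potent as peroxide, binomial 5-seed
# replicates) calibrated to the qualitative pattern of the real trial.
# The check passes when the protocol found by GRNN + GA has a *true*
# contamination probability within 0.02 of the best achievable anywhere
# in the search box.

library(disinfectr)

dir.create("results", showWarnings = FALSE)

checks <- lapply(1:5, function(seed) {
  chk <- recover_optimum_check(seed = seed)
  cat(sprintf(
    "seed %d: optimum (%.2f %%, %.2f %%, %.1f min)  true p %.4f  envelope %.4f  %s\n",
    seed, chk$best[["naocl"]], chk$best[["h2o2"]], chk$best[["time"]],
    chk$true_probability, chk$envelope_min,
    if (chk$pass) "PASS" else "FAIL"))
  chk
})

passes <- vapply(checks, `[[`, TRUE, "pass")
cat(sprintf("\n%d / %d seeds recover the envelope optimum within 0.02\n",
            sum(passes), length(passes)))

jsonlite::write_json(
  lapply(checks, function(chk) list(
    pass = chk$pass, best = as.list(round(chk$best, 3)),
    true_probability = chk$true_probability,
    envelope_min = chk$envelope_min, sigma = chk$sigma, seed = chk$seed)),
  "results/synthetic_validation.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("Wrote results/synthetic_validation.json\n")
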