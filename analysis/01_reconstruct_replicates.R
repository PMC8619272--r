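#!/usr/bin/env Rscript
# Stage 1: invert the published per-treatment mean +/- SE summaries into
# replicate-level observations.
#
# Replicates of 5 seeds can only show 0/20/40/60/80/100 % contamination,
# which makes the printed (mean, SE) pairs invertible by exhaustive search
# over the 56 possible replicate multisets. This run checks that all 19
# treatments invert uniquely and that the recovered replicates reproduce
# the printed summaries exactly after rounding.

library(disinfectr)

dir.create("results", showWarnings = FALSE)

trial <- disinfection_trial()
obs <- expand_replicates(trial)

stopifnot(nrow(obs) == 57L)
agg <- aggregate(contamination ~ naocl + h2o2 + time, obs,
                 function(v) c(mean = round(mean(v), 1),
                               se = round(sd(v) / sqrt(3), 2)))
key <- function(d) paste(d$naocl, d$h2o2, d$time)
idx <- match(key(trial), key(agg))
stopifnot(all(agg$contamination[idx, "mean"] == trial$mean),
          all(agg$contamination[idx, "se"] == trial$se))

write.csv(obs, "results/replicates.csv", row.names = FALSE)

wide <- do.call(rbind, lapply(seq_len(nrow(trial)), function(i) {
  reps <- reconstruct_replicates(trial$mean[i], trial$se[i])
  data.frame(trial[i, ], r1 = reps[1], r2 = reps[2], r3 = reps[3])
}))
write.csv(wide, "results/reconstruction_table.csv", row.names = FALSE)

cat("All 19 treatments reconstructed uniquely; 57 replicate observations\n")
cat("round-trip to the printed means (1 dp) and SEs (2 dp) exactly.\n")
cat("Wrote results/replicates.csv and results/reconstruction_table.csv\n")
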