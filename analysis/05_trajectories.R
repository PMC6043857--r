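#!/usr/bin/env Rscript
# Stage 5: model-implied trajectories and slope parallelism.
#
# Evaluates the fitted fixed-effects trajectories for a reference profile
# (man born 1935, first sample) at education 3 years below, at, and 3
# years above the center, ages 35-85, and summarizes the posterior of the
# pairwise linear-slope differences between education tiers.  Parallel
# trajectories (slope contrasts covering zero) are the signature of
# education shifting the level but not the rate of decline.
#
# Reads results/draws_<outcome>.csv from stage 3; writes
# results/trajectories_<outcome>.csv and results/slope_contrasts.csv.

suppressPackageStartupMessages(library(cogdecline))
contrasts <- NULL
for (o in c("va", "sk", "em")) {
  fit <- read_draws_csv(sprintf("results/draws_%s.csv", o))
  traj <- implied_trajectories(fit)
  utils::write.csv(traj, sprintf("results/trajectories_%s.csv", o),
                   row.names = FALSE)
  sc <- slope_difference_hdi(fit)
  sc$outcome <- o
  contrasts <- rbind(contrasts, sc)
  cat(sprintf("[%s] slope contrasts cover zero: %s\n", o,
              paste(sc$contains_zero, collapse = " ")))
}
utils::write.csv(contrasts, "results/slope_contrasts.csv",
                 row.names = FALSE)
print(contrasts, row.names = FALSE, digits = 3)
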