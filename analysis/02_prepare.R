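#!/usr/bin/env Rscript
# Stage 2: exclusions, T-standardization, centering, design matrices.
#
# Applies the study's person-level filters (earliest and latest cohort
# bands, education missing at every wave, education above 25 or below 6
# years), derives education as the maximum report over waves,
# T-standardizes each outcome on its first-occasion mean and SD, centers
# age/cohort/education at 62.9 years / 1933 / 10.2 years, and builds the
# 25-column fixed-effects design matrix on the pooled orthogonal age
# basis.
#
# Reads results/synthetic_cohort.csv; writes per outcome
# results/prepared_<outcome>.csv, results/design_<outcome>.csv and
# results/prep_meta_<outcome>.json.  Runtime: seconds.

suppressPackageStartupMessages(library(cogdecline))
dat <- read_cohort_csv("results/synthetic_cohort.csv")
cfg <- prep_config()              # study constants, exclusions, T-anchoring

for (o in c("va", "sk", "em")) {
  prep <- prepare_dataset(dat, o, cfg)
  write_prepared_csv(prep, sprintf("results/prepared_%s.csv", o),
                     sprintf("results/design_%s.csv", o))
  meta <- list(outcome = o, centers = as.list(prep$centers),
               basis_coef = as.list(prep$basis_coef),
               baseline = as.list(prep$baseline),
               exclusions = as.list(prep$exclusions),
               n_persons = length(prep$person_ids),
               n_rows = nrow(prep$data))
  jsonlite::write_json(meta, sprintf("results/prep_meta_%s.json", o),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("[%s] %d persons, %d rows; excluded: %s\n", o,
              length(prep$person_ids), nrow(prep$data),
              paste(names(prep$exclusions), prep$exclusions,
                    sep = "=", collapse = ", ")))
  cat(sprintf("[%s] first-occasion anchor: mean %.2f, SD %.2f (raw scale)\n",
              o, prep$baseline["mean"], prep$baseline["sd"]))
}
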