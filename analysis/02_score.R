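#!/usr/bin/env Rscript
# Score every member of the simulated cohort over the baseline window and
# summarize the Risk Vital Sign distribution. Reads the files written by
# 01_simulate.R through the package's claim readers (so the full file
# contract is exercised), excludes members with a prior coded PI, and
# writes the per-member score table.
#
# Writes: results/scores.csv, results/score_histogram.csv

suppressPackageStartupMessages(library(pirisk))

in_dir <- "results/synthetic"
members <- read_members(file.path(in_dir, "members.csv"))
claims <- read_claims(file.path(in_dir, "dx_claims.csv"),
                      file.path(in_dir, "rx_claims.csv"))
stopifnot(nrow(rejects(members)) == 0, nrow(rejects(claims$dx)) == 0)

wt <- default_weight_table()
rules <- scoring_rules()

part <- exclude_prior_pi(members, claims$dx, wt$pi_codes,
                         rules$window_end - 1)
message(sprintf("excluded %d of %d members for a prior coded PI diagnosis",
                nrow(part$excluded), nrow(members)))

scores <- score_cohort(part$retained, claims$dx, claims$rx, wt, rules)
write_scores(scores, "results/scores.csv")

hist <- dplyr::count(scores, total, category, name = "members")
readr::write_csv(hist, "results/score_histogram.csv")

mhr <- identify_mhr(scores, rules)
message(sprintf("score range %d-%d; %d members (%s%%) are medium-high risk (>= %d points)",
                min(scores$total), max(scores$total), length(mhr),
                proportion(length(mhr), nrow(scores), 1), rules$medium_min))
message(sprintf("category counts: %s",
                paste(sprintf("%s=%d", names(table(scores$category)),
                              table(scores$category)), collapse = ", ")))
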