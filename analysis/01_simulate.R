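#!/usr/bin/env Rscript
# Generate the synthetic health-plan cohort the downstream analyses run on:
# a 20,000-member roster with the published demographic marginals, baseline
# diagnosis/pharmacy claims (January-June 2016), follow-up claims
# (July 2016-June 2017), and the planted ground-truth labels.
#
# Writes: results/synthetic/{members,dx_claims,rx_claims,truth,followup_dx}.csv

suppressPackageStartupMessages(library(pirisk))

out_dir <- "results/synthetic"
cfg <- sim_config(n_members = 20000L, seed = 2016L)

sim <- generate_cohort(cfg, out_dir = out_dir)
fup <- generate_followup(cfg, sim$truth, out_dir = out_dir)

write_manifest(
  run_manifest(cfg, seed = cfg$seed,
               stage_counts = list(members = nrow(sim$members),
                                   dx_claims = nrow(sim$dx),
                                   rx_claims = nrow(sim$rx),
                                   followup_dx = nrow(fup))),
  file.path(out_dir, "manifest.yaml")
)

message(sprintf("cohort: %d members, %d baseline dx claims, %d pharmacy fills",
                nrow(sim$members), nrow(sim$dx), nrow(sim$rx)))
message(sprintf("planted: %d MHR, %d prior-PI; %d follow-up dx claims",
                sum(sim$truth$planted_mhr), sum(sim$truth$planted_prior_pi),
                nrow(fup)))
message(sprintf("files under %s", out_dir))
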