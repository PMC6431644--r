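#!/usr/bin/env Rscript
# Render the human-readable screening report from the pipeline result and
# reproduce the reference study's printed arithmetic (every percentage and
# the savings figure recomputed from its published tallies).
#
# Writes: results/report.md, results/printed_arithmetic.csv

suppressPackageStartupMessages(library(pirisk))

in_dir <- "results/synthetic"
members <- read_members(file.path(in_dir, "members.csv"))
claims <- read_claims(file.path(in_dir, "dx_claims.csv"),
                      file.path(in_dir, "rx_claims.csv"))
fup <- read_dx_claims(file.path(in_dir, "followup_dx.csv"))
res <- run_pipeline(cohort_config(), members, claims$dx, claims$rx,
                    followup_dx = fup)

md <- render_report(res$cohort_report, res$followup_report, "markdown")
writeLines(md, "results/report.md")
message("wrote results/report.md")

# printed arithmetic of the reference deployment, recomputed from tallies
k <- reference_counts()
arith <- tibble::tribble(
  ~quantity, ~numerator, ~denominator, ~value,
  "mhr_pct_of_cohort", k$n_mhr, k$n_main, proportion(k$n_mhr, k$n_main, 1),
  "focused_mhr_pct_of_cohort", k$n_focused_mhr, k$n_main,
    proportion(k$n_focused_mhr, k$n_main, 1),
  "new_pi_pct_of_focused_mhr", k$n_new_pi_patients, k$n_focused_mhr,
    proportion(k$n_new_pi_patients, k$n_focused_mhr, 1),
  "concerning_pct_of_focused_mhr", k$n_concerning_patients, k$n_focused_mhr,
    proportion(k$n_concerning_patients, k$n_focused_mhr, 1),
  "pi_nos_share_pct", k$pi_code_tally[["Immunodeficiency NOS"]],
    sum(k$pi_code_tally),
    proportion(k$pi_code_tally[["Immunodeficiency NOS"]], sum(k$pi_code_tally), 0),
  "sought_care_pct", k$utilization[["care"]], k$n_focused_mhr,
    proportion(k$utilization[["care"]], k$n_focused_mhr, 0),
  "savings_usd", k$n_new_pi_patients + k$n_concerning_patients,
    k$savings_per_patient_usd,
    estimate_savings(k$n_new_pi_patients + k$n_concerning_patients,
                     k$savings_per_patient_usd),
  "savings_musd", k$n_new_pi_patients + k$n_concerning_patients,
    k$savings_per_patient_usd,
    savings_in_millions(estimate_savings(
      k$n_new_pi_patients + k$n_concerning_patients, k$savings_per_patient_usd))
)
readr::write_csv(arith, "results/printed_arithmetic.csv")
message("reference-arithmetic check:")
print(as.data.frame(arith), row.names = FALSE)
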