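---
title: "The Risk Vital Sign: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Risk Vital Sign: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Why score infection claims?

Primary immunodeficiencies (PI) are inherited host-defense disorders.
Most affected people — especially those with the common antibody
deficiencies — are not born visibly ill; they accumulate an unusual burden
of ordinary infections over years before anyone measures an immunoglobulin.
Every one of those infections, and every antibiotic dispensed for it,
leaves a coded trace in administrative claims. The Risk Vital Sign turns
that trace into a single integer per health-plan member: a weighted
enumeration of infection-associated ICD-9/ICD-10 diagnosis codes plus a
pharmacy term for prolonged antibiotic exposure. It is a screening
prioritizer for clinical decision support, not a diagnostic test: members
scoring in the medium-high range are worth a clinician's second look, and
nothing more is claimed.

pirisk implements the score exactly as deployed in a published screening of
a large pediatric Medicaid health plan (185,892 members scored over a
six-month window, with a twelve-month follow-up re-analysis), together with
the surrounding population workflow and a synthetic-claims generator that
stands in for the protected data.

## The scoring model

For a member $m$ with diagnosis claims $C_m$ and antibiotic fills $F_m$
inside the analysis window, the score is

$$
S_m \;=\; \underbrace{\sum_{c \,\in\, C_m^{\text{base}}} w(c)}_{\text{base}}
\;+\; \underbrace{\max(0,\, E^{\text{OM}}_m - 4)}_{\text{otitis media}}
\;+\; \underbrace{\max(0,\, E^{\text{SIN}}_m - 2)}_{\text{sinusitis}}
\;+\; \underbrace{3 \sum_{r \,\in\, \text{runs}(F_m)} \left\lfloor |r| / 60 \right\rfloor}_{\text{pharmacy}}
$$

* **Base points.** Each claim whose code matches a weighted prefix outside
  the two episodic groups contributes its weight $w(c) \in \{1,2,3\}$:
  1 for generally mild infections (tonsillitis, pharyngitis), 2 for
  intermediate ones (pneumonia, cellulitis, UTI), 3 for severe ones
  (pneumocystis pneumonia, pneumococcal sepsis, bacterial meningitis).
  Every matching claim scores; there is no per-code cap. Claims matching no
  entry contribute nothing.
* **Episodic allowances.** Otitis media and sinusitis are so common in
  childhood that isolated occurrences carry no signal. Claims in these two
  groups are collapsed into episodes ($E^{\text{OM}}_m$, $E^{\text{SIN}}_m$)
  and only the 5th-and-subsequent otitis episode and the
  3rd-and-subsequent sinusitis episode score, one point each.
* **Pharmacy rule.** Antibiotic fills define half-open supply intervals
  $[\text{fill}, \text{fill} + \text{days supply})$. Intervals separated by
  at most 7 days are merged into continuous-therapy runs; each run awards
  3 points per completed 60 days, i.e. $3\lfloor|r|/60\rfloor$, so a 59-day
  run scores 0 and a 119-day run scores 3, not 6.

Categories follow the deployed cut-offs: **high** above 10 points,
**medium** for 8–10, **low** below 8. The medium and high categories
together form the medium-high-risk (MHR) set flagged for follow-up
($S_m \ge 8$).

### Operational choices the published description leaves open

* **What is an episode?** The deployment counts "episodes per year" without
  operationalizing them from dated claims. pirisk starts a new episode when
  a claim falls 30 or more days after the *first claim of the current
  episode* — the conventional claims heuristic for acute otitis media and
  sinusitis recurrence. The gap is configurable (`episode_gap_days`).
* **The boundary at exactly 4 (resp. 2) episodes.** The deployed rule is
  stated two ways that disagree at the boundary: "no points without at
  least 4 episodes per year" versus "1 point for each episode ... for the
  5th and subsequent". pirisk implements the parenthetical operational
  form: 4 otitis episodes score 0, the 5th scores the first point (and
  likewise 2/3rd for sinusitis). `score_episodic()` is exactly
  `max(0, episodes - free)`.
* **Per-year thresholds on other window lengths.** The allowances (4, 2)
  are applied to the analysis window as absolute counts regardless of its
  length, because the reference deployment itself applied them unchanged to
  a six-month window. No automatic scaling is performed.
* **Repeated severe codes.** Whether the same severe code on consecutive
  days should score repeatedly is unstated; pirisk scores every matching
  claim, applying episode logic only where the rule defines it (the two
  episodic groups). This keeps the score monotone in the claim set — adding
  a claim can never lower a member's score, a property the test suite
  checks by construction.
* **"Continuous" antibiotic therapy.** Continuity is undefined in the
  source description. pirisk merges supply intervals across gaps of at most
  `antibiotic_merge_gap_days = 7` days (refill slack); both the gap and the
  60-day course length are configurable.
* **A score of zero.** The deployed categories label scores 1–7 "low" and
  never name 0. pirisk reports 0 as category low but retains a
  `zero_score` flag so downstream consumers can distinguish "no signal"
  from "low signal".

### Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `otitis_free_episodes` | 4 | episodes | allowance before otitis scores |
| `sinusitis_free_episodes` | 2 | episodes | allowance before sinusitis scores |
| `episode_gap_days` | 30 | days | gap (from episode start) opening a new episode |
| `antibiotic_course_days` | 60 | days | length of one scoring course |
| `antibiotic_course_points` | 3 | points | award per completed course |
| `antibiotic_merge_gap_days` | 7 | days | refill slack treated as continuous |
| `medium_min` | 8 | points | lowest medium score; the MHR threshold |
| `high_min_exclusive` | 10 | points | highest medium score; above is high |
| `window_start`, `window_end` | 2016-01-01, 2016-07-01 | dates | half-open scoring window |

All of them live in a single `scoring_rules()` object that serializes to
YAML with these exact key names.

## Code matching

Codes are normalized before anything else: uppercased, periods and
surrounding whitespace stripped (`"j01.90"` → `"J0190"`); normalization is
idempotent. Lookup is longest-prefix within ICD version, the standard
grouper convention, because code lists mix 3–5 character prefixes. An entry
with version `"any"` matches claims of either version; at equal prefix
length a version-specific entry beats an `"any"` entry (a deterministic
tie-break the table invariants otherwise leave open). ICD-9 and ICD-10 are
never cross-walked: a claim scores only against entries of its own version
or `"any"`, because silent mapping would invent data.

The built-in `default_weight_table()` is an illustrative subset
(~40 prefixes) anchored on the named exemplar codes; the full 350+ entry
weighting used in the reference deployment is supplementary material of
that study and can be supplied as CSV via `read_weight_table()`. The PI
family (ICD-10 D80–D84, ICD-9 279) is validated to be disjoint from the
scored infection prefixes.

## The cohort workflow

`run_pipeline()` reproduces the deployment's stepwise cohort analysis, with
every stage's input/output counts recorded in a waterfall table:

1. **Exclusion.** The single exclusion criterion: any diagnosis claim on or
   before the baseline window end matching a PI prefix removes the member
   (the score screens for *undiagnosed* disease).
2. **Scoring** over the baseline window; members with no claims score 0.
3. **MHR extraction**: members at `medium_min` or above.
4. **Follow-up retention.** The focused MHR cohort is the subset still
   enrolled through the follow-up window (`enrolled_to` at or past its
   end). Retained MHR members carry an `intervened` flag mirroring the
   deployment's physician-letter notification; no causal claim is attached
   to it (the deployment did not control for it either).
5. **Re-analysis.** A retained member becomes a *new PI case* if any
   follow-up claim matches a PI prefix; *concerning diagnoses* (cellulitis,
   abscess, recurrent otitis media, ... — ten referral-worthy groups) are
   tallied among the rest. Both tallies count *codes*, not members, with
   integer percentages of the code totals as denominators — matching how
   the reference tables are captioned (46 PI codes from 41 members;
   59 concerning codes from 57 members). The pipeline wires the follow-up
   window into `detect_concerning()`; the function itself takes any claim
   set, so the baseline window can be examined the same way.
6. **Savings.** Identified patients (new PI plus concerning) times the
   annual post-diagnosis per-patient savings, $78,166 by default, with a
   millions-rounded convenience form.

### Rounding

Every printed percentage uses `proportion()`: $100\,n/d$ rounded **half
away from zero** (base R's `round()` rounds half to even, which disagrees
with published claims-report arithmetic). The reference study's own tables
are not perfectly consistent under any single rounding rule — a few rows
appear truncated instead of rounded — so pirisk applies half-up uniformly
and documents the choice rather than matching each printed digit.

## The synthetic-claims generator

Real claims are protected health information, so the package ships a
generator whose output has the statistical structure the pipeline assumes.
Its defaults are the study conditions:

* **Demographics** drawn from the published main-cohort marginals
  (ethnicity, sex, five pediatric age bands; ages are exact at the
  baseline start by construction).
* **Background infections**: per-member Poisson counts with means 1.5 /
  0.2 / 0.02 claims per baseline window for mild / intermediate / severe
  codes. Poisson is the minimal claims-count model; a negative-binomial
  option (`dispersion`) is exposed for over-dispersion. Background codes
  are sampled from the weighted entries *outside* the concerning-diagnosis
  families, so follow-up tallies reflect planted conversions only; the
  episodic codes that survive that filter stay in the mild pool, because
  otitis/sinusitis codes are the modal mild claims of a pediatric
  population and mostly score nothing under the allowances. (An
  all-scoring mild pool would push roughly 0.4% of background members over
  the MHR threshold — incompatible with the planted MHR fraction being
  recoverable; the diluted pool leaves ~0.17%.)
* **Episode bursts**: a small fraction of members receive otitis
  (episodes 2–6) or sinusitis (1–4) bursts, spaced exactly one episode gap
  apart so the planted episode count is unambiguous under the gap rule.
* **Long antibiotic courses**: occasional fills of 30–120 days supply.
* **Planted phenotypes**: a fraction 0.012 of members (the published MHR
  rate) receive three severe codes — 9 points, guaranteeing MHR membership
  by construction — and a fraction 0.002 receive a baseline PI code and
  must be caught by the exclusion stage. Follow-up outcomes are pre-drawn
  per planted-MHR member (PI conversion 0.038, concerning conversion
  0.053, mutually exclusive — the published focused-MHR outcome rates) and
  recorded in a ground-truth file; `generate_followup()` materializes them
  as claims, with PI labels drawn from the published six-label code
  distribution and concerning groups from the published ten-group one.
* **Retention**: members remain enrolled through follow-up with
  probability 1068/2188, the published focused-MHR retention; retention is
  encoded in `enrolled_to`, so the *pipeline*, not the truth file, decides
  who is retained.

Everything derives from a single mandatory seed; regeneration is
byte-identical. The truth file makes parameter-recovery tests possible:
the MHR set must contain every planted-MHR member, and the exclusion set
must equal the planted prior-PI set exactly.

### What the generator does not emulate

No seasonality, no ICD code co-occurrence structure, no correlation
between demographics and infection burden, no non-antibiotic pharmacy
claims, and a much lower per-member claim volume than a real plan (the
reference population averaged ~48 codes per member across all claim types;
the generator only draws the scored subset). Passing the planted-recovery
tests therefore shows the pipeline machinery is correct under the model's
assumptions — it says nothing about the score's clinical sensitivity or
specificity on real claims, which only a deployment can measure.

## Numerical and degenerate-input conventions

Dates are ISO-8601 throughout; all intervals (enrollment, scoring windows,
supply) are half-open `[start, end)`, making day arithmetic unambiguous.
Readers never silently drop rows: each returns accepted records plus a
rejects table with one reason per refused row, and
`rows in = accepted + rejected` always holds. Empty claim sets score 0;
empty files with headers parse to empty collections. Claims outside the
scoring window are a validation error unless the caller opts into
filtering. Ages outside the published 0–64 bands fall into an explicit
`"other"` band rather than being dropped. Scoring involves no randomness,
so there are no ties to break; the pipeline is bit-identical on re-runs.

## Problem sizes

The test suite exercises the oracle-equivalence property on 1,000 random
claim histories against an independent brute-force scorer (naive per-entry
matching, day-grid pharmacy accounting), planted recovery on a
5,000-member cohort, goodness-of-fit on 10,000 members, and a 1/100-scale
noise-free waterfall fixture (1,859 members) whose stage counts are fixed
by construction. The analysis scripts under `analysis/` run a 20,000-member
cohort; `scripts/acceptance.R` re-runs the pipeline at 50,000 members.
These sizes give stable stochastic checks while keeping a full run in
seconds.

## Known limitations

The default weight table is a teaching-sized approximation; serious use
requires the full clinical weighting as a user-supplied table. Utilization
reporting (care-seeking, PCP visits, labs, referrals) requires an optional
event file because claims alone cannot distinguish those encounter types;
without it the pipeline reports utilization as unavailable. The savings
estimate is a multiplication by a published per-patient figure, not a cost
model. And the score itself is a deterministic point system — no
calibration, no probabilistic risk, no learned weights — because that is
what was deployed and validated.
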