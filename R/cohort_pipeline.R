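#' Cohort configuration
#'
#' Fixes the two analysis windows and all scoring/economic parameters of a
#' screening run. Defaults mirror the published deployment: a six-month
#' baseline (January-June 2016) scored for risk, a twelve-month follow-up
#' (July 2016-June 2017) re-analyzed for new PI diagnoses, and a
#' post-diagnosis savings of $78,166 per PI patient per year.
#'
#' @param baseline_start,baseline_end baseline scoring window, half-open.
#' @param followup_start,followup_end follow-up window, half-open; must come
#'   after the baseline and not overlap it.
#' @param rules a [scoring_rules()]; its window is forced to the baseline.
#' @param table a [weight_table()].
#' @param savings_per_patient_usd annual post-diagnosis savings per
#'   identified PI patient (default 78166 USD).
#' @return an object of class `pirisk_cohort_config`.
#' @export
cohort_config <- function(baseline_start = as.Date("2016-01-01"),
                          baseline_end = as.Date("2016-07-01"),
                          followup_start = as.Date("2016-07-01"),
                          followup_end = as.Date("2017-07-01"),
                          rules = scoring_rules(),
                          table = default_weight_table(),
                          savings_per_patient_usd = 78166) {
  baseline_start <- as.Date(baseline_start); baseline_end <- as.Date(baseline_end)
  followup_start <- as.Date(followup_start); followup_end <- as.Date(followup_end)
  if (!(baseline_start < baseline_end && followup_start < followup_end)) {
    abort_validation("cohort_config: windows must have positive length")
  }
  if (followup_start < baseline_end) {
    abort_validation("cohort_config: follow-up must start at or after baseline end")
  }
  if (savings_per_patient_usd < 0) {
    abort_validation("cohort_config: savings must be non-negative")
  }
  rules$window_start <- baseline_start
  rules$window_end <- baseline_end
  structure(list(
    baseline_start = baseline_start, baseline_end = baseline_end,
    followup_start = followup_start, followup_end = followup_end,
    rules = rules, table = table,
    savings_per_patient_usd = savings_per_patient_usd
  ), class = "pirisk_cohort_config")
}

# index of the PI prefix matching each claim (NA = not a PI code)
match_pi <- function(dx_claims, pi_codes) {
  match_longest_prefix(dx_claims$code, dx_claims$icd_version, pi_codes)
}

#' Exclude members with a prior coded PI diagnosis
#'
#' The screen's single exclusion criterion: any diagnosis claim on or before
#' the baseline window end matching a PI prefix removes the member before
#' scoring. The partition is exhaustive and disjoint.
#'
#' @param members roster.
#' @param dx_claims diagnosis claims (normalized codes).
#' @param pi_codes PI prefix table (`table$pi_codes` of a [weight_table()]).
#' @param window_end last date (inclusive) on which a PI claim counts as prior.
#' @return list with `retained` and `excluded` member tibbles.
#' @export
exclude_prior_pi <- function(members, dx_claims, pi_codes, window_end) {
  window_end <- as.Date(window_end)
  prior <- dx_claims[dx_claims$service_date <= window_end, ]
  hit <- !is.na(match_pi(prior, pi_codes))
  excluded_ids <- unique(prior$member_id[hit])
  is_excluded <- members$member_id %in% excluded_ids
  list(retained = members[!is_excluded, ], excluded = members[is_excluded, ])
}

#' Extract the medium-high-risk (MHR) set
#'
#' Members scoring at or above the medium-risk threshold -- exactly the
#' union of the medium and high categories.
#'
#' @param scores tibble from [score_cohort()].
#' @param rules a [scoring_rules()].
#' @return character vector of MHR member ids.
#' @export
identify_mhr <- function(scores, rules) {
  stopifnot(inherits(rules, "pirisk_rules"))
  scores$member_id[scores$total >= rules$medium_min]
}

AGE_BANDS <- tibble::tibble(
  band = c("0-5", "6-12", "13-18", "19-21", "22-64"),
  lo = c(0, 6, 13, 19, 22),
  hi = c(5, 12, 18, 21, 64)
)

#' Age in completed years at a date
#'
#' @param birth_date,at Date vectors.
#' @return integer ages.
#' @export
age_at <- function(birth_date, at) {
  by <- as.POSIXlt(birth_date); ay <- as.POSIXlt(at)
  age <- ay$year - by$year
  before_birthday <- ay$mon < by$mon | (ay$mon == by$mon & ay$mday < by$mday)
  as.integer(age - before_birthday)
}

age_band_of <- function(age) {
  out <- rep("other", length(age))
  for (i in seq_len(nrow(AGE_BANDS))) {
    out[age >= AGE_BANDS$lo[i] & age <= AGE_BANDS$hi[i]] <- AGE_BANDS$band[i]
  }
  out
}

#' Stratified demographic counts and percentages
#'
#' Tallies the cohort by ethnicity, sex and age band (ages 0-5, 6-12, 13-18,
#' 19-21, 22-64, computed at the analysis date). Percentages are rounded
#' half-up to `decimals` places against the cohort size; ages outside 0-64
#' fall into an `"other"` band and are reported, not dropped.
#'
#' @param members roster.
#' @param analysis_date date at which ages are computed (the pipeline uses
#'   the baseline window start).
#' @param strata which stratifications to tabulate.
#' @param decimals decimal places for percentages (default 1, as printed in
#'   screening reports).
#' @return tibble with columns `stratification`, `stratum`, `n`, `pct`.
#' @export
demographics_table <- function(members, analysis_date,
                               strata = c("ethnicity", "sex", "age_band"),
                               decimals = 1) {
  analysis_date <- as.Date(analysis_date)
  n_total <- nrow(members)
  if (n_total == 0) {
    return(tibble::tibble(stratification = character(), stratum = character(),
                          n = integer(), pct = numeric()))
  }
  age <- age_at(members$birth_date, analysis_date)
  values <- list(
    ethnicity = factor(members$ethnicity, levels = ETHNICITY_LEVELS),
    sex = factor(members$sex, levels = SEX_LEVELS),
    age_band = factor(age_band_of(age), levels = c(AGE_BANDS$band, "other"))
  )
  out <- lapply(intersect(strata, names(values)), function(s) {
    tab <- table(values[[s]])
    tab <- tab[tab > 0 | names(tab) != "other"]  # keep empty named strata, drop empty "other"
    tibble::tibble(
      stratification = s,
      stratum = names(tab),
      n = as.integer(tab),
      pct = proportion(as.integer(tab), n_total, decimals)
    )
  })
  dplyr::bind_rows(out)
}

#' Detect newly coded PI diagnoses at follow-up
#'
#' A medium-high-risk member counts as a new PI case iff at least one
#' follow-up diagnosis claim matches a PI prefix. The tally counts codes,
#' not members (one member can contribute several distinct PI codes), with
#' each label's share expressed as an integer percentage of all PI codes.
#'
#' @param mhr_ids MHR member ids (already free of baseline PI by exclusion).
#' @param followup_dx follow-up diagnosis claims.
#' @param pi_codes PI prefix table with labels.
#' @return list with `members` (ids) and `tally`
#'   (tibble `label`, `n_codes`, `pct`).
#' @export
detect_new_pi <- function(mhr_ids, followup_dx, pi_codes) {
  dx <- followup_dx[followup_dx$member_id %in% mhr_ids, ]
  idx <- match_pi(dx, pi_codes)
  hits <- dx[!is.na(idx), ]
  hits$label <- pi_codes$label[idx[!is.na(idx)]]
  members <- unique(hits$member_id)
  if (nrow(hits) == 0) {
    return(list(members = character(),
                tally = tibble::tibble(label = character(), n_codes = integer(),
                                       pct = numeric())))
  }
  tally <- hits |>
    dplyr::count(.data$label, name = "n_codes", sort = TRUE) |>
    dplyr::mutate(pct = proportion(.data$n_codes, sum(.data$n_codes), 0))
  list(members = members, tally = tibble::as_tibble(tally))
}

#' Tally concerning (non-PI) diagnoses among MHR members
#'
#' Concerning diagnoses are coded conditions judged to warrant referral to a
#' clinical immunologist (cellulitis, abscess, recurrent otitis media, ...).
#' A member is flagged iff they carry at least one concerning code and no PI
#' code; the tally counts codes per group with integer percentages of all
#' concerning codes.
#'
#' @param mhr_ids MHR member ids.
#' @param dx_claims diagnosis claims of the window being examined.
#' @param concerning_groups group prefix table
#'   (`table$concerning_groups` of a [weight_table()]).
#' @param pi_members ids already identified as PI cases; their codes are
#'   still tallied but they are not flagged as concerning-only members.
#' @param groups which groups to tabulate (default all); unknown names are a
#'   validation error.
#' @return list with `members` (flagged ids) and `tally`
#'   (tibble `group`, `label`, `n_codes`, `pct`).
#' @export
detect_concerning <- function(mhr_ids, dx_claims, concerning_groups,
                              pi_members = character(), groups = NULL) {
  if (!is.null(groups)) {
    unknown <- setdiff(groups, unique(concerning_groups$group))
    if (length(unknown) > 0) {
      abort_validation(sprintf("detect_concerning: unknown group(s): %s",
                               paste(unknown, collapse = ", ")))
    }
    concerning_groups <- concerning_groups[concerning_groups$group %in% groups, ]
  }
  dx <- dx_claims[dx_claims$member_id %in% mhr_ids, ]
  idx <- match_longest_prefix(dx$code, dx$icd_version, concerning_groups)
  hits <- dx[!is.na(idx), ]
  if (nrow(hits) == 0) {
    return(list(members = character(),
                tally = tibble::tibble(group = character(), label = character(),
                                       n_codes = integer(), pct = numeric())))
  }
  hits$group <- concerning_groups$group[idx[!is.na(idx)]]
  hits$label <- concerning_groups$label[idx[!is.na(idx)]]
  members <- setdiff(unique(hits$member_id), pi_members)
  tally <- hits |>
    dplyr::count(.data$group, .data$label, name = "n_codes", sort = TRUE) |>
    dplyr::mutate(pct = proportion(.data$n_codes, sum(.data$n_codes), 0))
  list(members = members, tally = tibble::as_tibble(tally))
}

#' Percentage with half-up rounding
#'
#' The single arithmetic used for every percentage the pipeline prints:
#' `100 * numerator / denominator`, rounded half away from zero to
#' `decimals` places.
#'
#' @param numerator,denominator non-negative counts; zero denominator is a
#'   validation error.
#' @param decimals decimal places.
#' @return numeric percentage(s).
#' @examples
#' proportion(2188, 185892, 1)  # 1.2
#' proportion(41, 1068, 1)      # 3.8
#' @export
proportion <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) {
    abort_validation("proportion: denominator must be positive")
  }
  if (any(numerator < 0)) {
    abort_validation("proportion: numerator must be non-negative")
  }
  round_half_up(100 * numerator / denominator, decimals)
}

#' Projected annual savings from early PI identification
#'
#' Multiplies the number of identified (confirmed plus suspected) PI
#' patients by the annual post-diagnosis per-patient savings.
#'
#' @param n_identified count of identified patients.
#' @param per_patient_usd annual savings per patient (default 78166 USD).
#' @return savings in USD.
#' @seealso [savings_in_millions()]
#' @export
estimate_savings <- function(n_identified, per_patient_usd = 78166) {
  if (any(n_identified < 0) || any(per_patient_usd < 0)) {
    abort_validation("estimate_savings: inputs must be non-negative")
  }
  n_identified * per_patient_usd
}

#' @rdname estimate_savings
#' @param usd dollar amount.
#' @return `savings_in_millions`: the amount in millions of USD, half-up
#'   rounded to one decimal (7,660,268 reports as 7.7).
#' @export
savings_in_millions <- function(usd) {
  round_half_up(usd / 1e6, 1)
}

#' Tally follow-up healthcare utilization
#'
#' Utilization ("sought care", PCP visits, laboratory evaluation, specialist
#' referral) cannot be told apart from diagnosis claims alone, so it is
#' driven by an optional event file. Percentages use the retained MHR count
#' as denominator.
#'
#' @param events data frame with `member_id`, `event_date`, `event_type`
#'   (one of `care`, `pcp_visit`, `lab`, `referral`), or `NULL`.
#' @param mhr_retained_ids ids of MHR members still enrolled at follow-up.
#' @return tibble `event_type`, `n_members`, `pct`, or `NULL` when no event
#'   file is available.
#' @export
tally_utilization <- function(events, mhr_retained_ids) {
  if (is.null(events)) return(NULL)
  n <- length(mhr_retained_ids)
  ev <- events[events$member_id %in% mhr_retained_ids, ]
  known <- c("care", "pcp_visit", "lab", "referral")
  sought <- unique(ev$member_id)  # any event counts as having sought care
  counts <- vapply(known, function(t) {
    if (t == "care") length(sought)
    else length(unique(ev$member_id[ev$event_type == t]))
  }, 1L)
  tibble::tibble(
    event_type = known,
    n_members = as.integer(unname(counts)),
    pct = if (n > 0) unname(proportion(counts, n, 1)) else rep(NA_real_, length(known))
  )
}

#' Run the full screening pipeline
#'
#' Executes the population workflow stage by stage: prior-PI exclusion,
#' baseline scoring, MHR extraction, follow-up retention, new-PI detection,
#' concerning-diagnosis tally, utilization, and the savings estimate. Every
#' stage's input and output counts are recorded in a waterfall table so the
#' cohort attrition is reconstructible. Deterministic: identical inputs and
#' config give identical reports.
#'
#' @param config a [cohort_config()].
#' @param members,dx_claims,rx_claims baseline data.
#' @param followup_dx follow-up diagnosis claims (`NULL` skips follow-up).
#' @param events optional utilization events (see [tally_utilization()]).
#' @return list of class `pirisk_pipeline_result` with elements
#'   `cohort_report`, `followup_report`, `waterfall`, `scores`,
#'   `mhr` (tibble of MHR members with an `intervened` flag).
#' @export
run_pipeline <- function(config, members, dx_claims, rx_claims,
                         followup_dx = NULL, events = NULL) {
  stopifnot(inherits(config, "pirisk_cohort_config"))
  table <- config$table
  rules <- config$rules

  n_total <- nrow(members)
  excl <- exclude_prior_pi(members, dx_claims, table$pi_codes,
                           config$baseline_end - 1)
  n_excluded <- nrow(excl$excluded)
  scored_members <- excl$retained

  scores <- score_cohort(scored_members, dx_claims, rx_claims, table, rules)
  histogram <- scores |>
    dplyr::count(.data$total, name = "count") |>
    dplyr::arrange(.data$total)

  mhr_ids <- identify_mhr(scores, rules)
  mhr_members <- scored_members[scored_members$member_id %in% mhr_ids, ]

  # focused MHR cohort: members still enrolled through the follow-up window
  retained <- mhr_members[mhr_members$enrolled_to >= config$followup_end, ]
  mhr <- mhr_members
  mhr$retained <- mhr$member_id %in% retained$member_id
  # every retained MHR member triggers the physician-letter intervention;
  # kept as a flag so follow-up reports can stratify by it
  mhr$intervened <- mhr$retained

  cohort_report <- list(
    n_total = n_total,
    n_excluded_prior_pi = n_excluded,
    n_scored = nrow(scored_members),
    risk_histogram = histogram,
    n_mhr = length(mhr_ids),
    mhr_pct_of_cohort = proportion(length(mhr_ids), max(n_total, 1), 1),
    demographics_main = demographics_table(scored_members, config$baseline_start),
    demographics_mhr = demographics_table(retained, config$baseline_start)
  )

  followup_report <- NULL
  new_pi <- list(members = character(),
                 tally = tibble::tibble(label = character(),
                                        n_codes = integer(), pct = numeric()))
  concerning <- list(members = character(),
                     tally = tibble::tibble(group = character(),
                                            label = character(),
                                            n_codes = integer(),
                                            pct = numeric()))
  if (!is.null(followup_dx)) {
    fup <- followup_dx[followup_dx$service_date >= config$followup_start &
                         followup_dx$service_date < config$followup_end, ]
    new_pi <- detect_new_pi(retained$member_id, fup, table$pi_codes)
    concerning <- detect_concerning(retained$member_id, fup,
                                    table$concerning_groups,
                                    pi_members = new_pi$members)
    n_identified <- length(new_pi$members) + length(concerning$members)
    followup_report <- list(
      n_mhr_retained = nrow(retained),
      n_new_pi = length(new_pi$members),
      pi_code_tally = new_pi$tally,
      n_concerning = length(concerning$members),
      concerning_tally = concerning$tally,
      utilization = tally_utilization(events, retained$member_id),
      n_identified = n_identified,
      estimated_savings_usd = estimate_savings(n_identified,
                                               config$savings_per_patient_usd),
      estimated_savings_musd = savings_in_millions(
        estimate_savings(n_identified, config$savings_per_patient_usd))
    )
  }

  waterfall <- tibble::tibble(
    stage = c("roster", "prior_pi_exclusion", "scored", "mhr",
              "mhr_retained_followup", "new_pi", "concerning_diagnosis"),
    n_in = c(n_total, n_total, nrow(scored_members), nrow(scored_members),
             length(mhr_ids), nrow(retained), nrow(retained)),
    n_out = c(n_total, nrow(scored_members), nrow(scored_members),
              length(mhr_ids), nrow(retained), length(new_pi$members),
              length(concerning$members)),
    pct_of_roster = proportion(
      c(n_total, nrow(scored_members), nrow(scored_members), length(mhr_ids),
        nrow(retained), length(new_pi$members), length(concerning$members)),
      max(n_total, 1), 1)
  )
  waterfall$n_dropped <- waterfall$n_in - waterfall$n_out

  structure(list(
    cohort_report = cohort_report,
    followup_report = followup_report,
    waterfall = waterfall,
    scores = scores,
    mhr = mhr
  ), class = "pirisk_pipeline_result")
}

#' @export
print.pirisk_pipeline_result <- function(x, ...) {
  cr <- x$cohort_report
  cat("<pirisk_pipeline_result>\n")
  cat(sprintf("  %d members; %d excluded for prior PI; %d scored; %d MHR (%.1f%%)\n",
              cr$n_total, cr$n_excluded_prior_pi, cr$n_scored, cr$n_mhr,
              cr$mhr_pct_of_cohort))
  if (!is.null(x$followup_report)) {
    fr <- x$followup_report
    cat(sprintf("  follow-up: %d retained; %d new PI; %d concerning; est. savings $%.1fM\n",
                fr$n_mhr_retained, fr$n_new_pi, fr$n_concerning,
                fr$estimated_savings_musd))
  }
  invisible(x)
}
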