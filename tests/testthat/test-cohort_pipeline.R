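wt <- default_weight_table()

test_that("members with a prior coded PI are excluded, all others retained", {
  members <- member_tbl(sprintf("E%02d", 1:10))
  dx <- dx_tbl(c("E01", "E02", "E03", "E04"),
               c("2016-02-01", "2016-03-01", "2016-04-01", "2016-08-15"),
               c("D839", "D8021", "J0300", "D849"))
  part <- exclude_prior_pi(members, dx, wt$pi_codes, as.Date("2016-06-30"))
  # E01 (D83 family) and E02 (D80 family) go; E03 has no PI code; E04's PI
  # claim falls after the window end
  expect_setequal(part$excluded$member_id, c("E01", "E02"))
  expect_equal(nrow(part$retained), 8)
  expect_equal(nrow(part$retained) + nrow(part$excluded), 10)
  expect_length(intersect(part$retained$member_id, part$excluded$member_id), 0)
})

test_that("the MHR set is exactly the members at or above 8 points", {
  rules <- window_rules()
  scores <- tibble::tibble(member_id = c("a", "b", "c", "d"),
                           total = c(7L, 8L, 10L, 11L))
  expect_setequal(identify_mhr(scores, rules), c("b", "c", "d"))
  expect_length(identify_mhr(tibble::tibble(member_id = "a", total = 0L), rules), 0)
})

test_that("demographics reproduce the published main-cohort percentages", {
  counts <- reference_counts()
  # roster with the published ethnicity and age-band marginals; the two
  # stratifications are independent columns so both can be exact
  eth <- rep(names(counts$main_ethnicity), counts$main_ethnicity)
  ages <- rep(c(3L, 9L, 15L, 20L, 40L), counts$main_age)
  n <- length(eth)
  at <- as.Date("2016-01-01")
  members <- tibble::tibble(
    member_id = sprintf("D%06d", seq_len(n)),
    birth_date = at - (ages * 366L),  # mid-band ages; band is what matters
    sex = "female",
    ethnicity = eth,
    enrolled_from = at,
    enrolled_to = as.Date("2017-07-01")
  )
  demo <- demographics_table(members, at)
  g <- function(strat, stratum) demo[demo$stratification == strat &
                                       demo$stratum == stratum, ]
  expect_equal(g("ethnicity", "hispanic")$pct, 59.9)
  expect_equal(g("ethnicity", "alaskan_american_indian")$n, 542L)
  expect_equal(g("age_band", "0-5")$pct, 18.9)
  expect_equal(g("age_band", "6-12")$pct, 48.4)  # 89948/185892, half-up
  # percentage closure within rounding slack
  for (s in unique(demo$stratification)) {
    expect_lt(abs(sum(demo$pct[demo$stratification == s]) - 100), 0.1 * nrow(demo))
  }
  # counts partition the roster
  expect_equal(sum(demo$n[demo$stratification == "age_band"]), n)
})

test_that("focused-MHR age skew matches the published 41% under-5 share", {
  counts <- reference_counts()
  expect_equal(proportion(counts$mhr_age[["0-5"]], counts$n_focused_mhr, 1), 41.1)
  expect_equal(round_half_up(proportion(counts$mhr_age[["0-5"]],
                                        counts$n_focused_mhr, 1), 0), 41)
  # a single member is 100% of each of its strata
  demo1 <- demographics_table(member_tbl("solo"), as.Date("2016-01-01"))
  expect_true(all(demo1$pct[demo1$n > 0] == 100))
})

test_that("new PI detection tallies codes with integer shares of the code total", {
  # 46 PI codes over 43 members: 37 NOS, 3 IgA, 3 IgM, 1 subclass, 1 CVID,
  # 1 other; three members carry two codes each (hence 41 distinct NOS+IgA
  # members is not required -- codes, not members, are tallied)
  ids <- sprintf("F%02d", 1:43)
  codes <- c(rep("D849", 37), rep("D802", 3), rep("D804", 3), "D803", "D839", "D821")
  owner <- c(ids[1:37], ids[1:3], ids[38:40], ids[41], ids[42], ids[43])
  fup <- dx_tbl(owner, rep("2016-09-15", 46), codes)
  res <- detect_new_pi(ids, fup, wt$pi_codes)
  expect_setequal(res$members, ids)
  tly <- res$tally
  expect_equal(sum(tly$n_codes), 46L)
  expect_equal(tly$pct[tly$label == "Immunodeficiency NOS"], 80)
  expect_equal(tly$n_codes[tly$label == "Immunodeficiency NOS"], 37L)
  expect_equal(tly$pct[tly$label == "Selective IgA deficiency"], 7)
  expect_equal(tly$pct[tly$label == "IgG subclass deficiency"], 2)

  none <- detect_new_pi(ids, dx_tbl("F01", "2016-09-15", "J0300"), wt$pi_codes)
  expect_length(none$members, 0)
  expect_equal(nrow(none$tally), 0)
})

test_that("concerning-diagnosis tallies count codes and flag non-PI members", {
  counts <- reference_counts()$concerning_tally
  code_for <- c(cellulitis = "L0390", abscess = "L0291",
                recurrent_otitis_media = "H6690", recurrent_sinusitis = "J329",
                bacterial_pneumonia = "J159", osteomyelitis = "M869",
                mastoiditis = "H709", pulmonary_tuberculosis = "A159",
                lymphadenitis = "L040", atypical_mycobacterial = "A319")
  codes <- rep(code_for[names(counts)], counts)
  ids <- sprintf("G%02d", seq_along(codes))
  dx <- dx_tbl(ids, rep("2016-10-01", length(codes)), unname(codes))
  res <- detect_concerning(ids, dx, wt$concerning_groups)
  expect_equal(sum(res$tally$n_codes), 59L)
  expect_equal(res$tally$n_codes[res$tally$group == "cellulitis"], 18L)
  expect_equal(res$tally$n_codes[res$tally$group == "abscess"], 14L)
  expect_length(res$members, 59)

  # a member already identified as PI is not flagged again
  res2 <- detect_concerning(ids, dx, wt$concerning_groups, pi_members = ids[1])
  expect_length(res2$members, 58)

  # two groups -> exactly two nonzero rows
  two <- detect_concerning(c("x", "y"),
                           dx_tbl(c("x", "y"), rep("2016-10-01", 2),
                                  c("L0390", "J159")),
                           wt$concerning_groups)
  expect_equal(nrow(two$tally), 2)

  empty <- detect_concerning("x", dx_tbl("x", "2016-10-01", "J0300"),
                             wt$concerning_groups)
  expect_equal(nrow(empty$tally), 0)
  expect_error(detect_concerning("x", dx_tbl("x", "2016-10-01", "L0390"),
                                 wt$concerning_groups, groups = "nonsense"),
               class = "pirisk_validation_error")
})

test_that("percentage arithmetic uses half-up rounding", {
  expect_equal(proportion(2188, 185892, 1), 1.2)
  expect_equal(proportion(41, 1068, 1), 3.8)
  expect_equal(proportion(57, 1068, 1), 5.3)
  expect_equal(proportion(0, 500, 2), 0)
  expect_equal(proportion(1, 8, 1), 12.5)
  expect_equal(proportion(1, 800, 1), 0.1)  # 0.125 rounds half-up to 0.1? no: 0.125 -> 0.1
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_error(proportion(1, 0), class = "pirisk_validation_error")
  expect_error(proportion(-1, 10), class = "pirisk_validation_error")
})

test_that("savings projections multiply identified patients by per-patient savings", {
  expect_equal(estimate_savings(98), 7660268)
  expect_equal(savings_in_millions(estimate_savings(98)), 7.7)
  expect_equal(estimate_savings(1), 78166)
  expect_equal(estimate_savings(0), 0)
  expect_error(estimate_savings(-1), class = "pirisk_validation_error")
})

test_that("utilization tallies reproduce the published follow-up rates", {
  counts <- reference_counts()
  n <- counts$n_focused_mhr
  ids <- sprintf("U%04d", seq_len(n))
  ev <- dplyr::bind_rows(
    tibble::tibble(member_id = ids[1:950], event_date = as.Date("2016-10-01"),
                   event_type = "care"),
    tibble::tibble(member_id = ids[1:555], event_date = as.Date("2016-11-01"),
                   event_type = "pcp_visit"),
    tibble::tibble(member_id = ids[1:220], event_date = as.Date("2016-12-01"),
                   event_type = "lab"),
    tibble::tibble(member_id = ids[1:35], event_date = as.Date("2017-01-01"),
                   event_type = "referral")
  )
  u <- tally_utilization(ev, ids)
  expect_equal(u$pct[u$event_type == "care"], 89.0)       # 950/1068
  expect_equal(u$pct[u$event_type == "pcp_visit"], 52.0)  # 555/1068
  expect_equal(u$pct[u$event_type == "lab"], 20.6)        # 220/1068, prints as 21
  expect_equal(u$pct[u$event_type == "referral"], 3.3)    # 35/1068
  expect_null(tally_utilization(NULL, ids))
})

test_that("the pipeline conserves counts at every waterfall stage and is deterministic", {
  cfg <- sim_config(n_members = 2000, seed = 5)
  sim <- generate_cohort(cfg)
  fup <- generate_followup(cfg, sim$truth)
  cc <- cohort_config()
  res <- run_pipeline(cc, sim$members, sim$dx, sim$rx, followup_dx = fup)

  cr <- res$cohort_report
  expect_equal(cr$n_scored, cr$n_total - cr$n_excluded_prior_pi)
  expect_equal(sum(cr$risk_histogram$count), cr$n_scored)
  expect_equal(res$waterfall$n_dropped, res$waterfall$n_in - res$waterfall$n_out)
  expect_equal(cr$n_mhr, sum(res$scores$total >= cc$rules$medium_min))

  # no member excluded for prior PI can surface as a new PI detection
  excluded <- setdiff(sim$members$member_id, res$scores$member_id)
  fr <- res$followup_report
  expect_length(intersect(excluded, res$mhr$member_id), 0)
  new_pi <- detect_new_pi(res$mhr$member_id[res$mhr$retained], fup, wt$pi_codes)
  expect_length(intersect(excluded, new_pi$members), 0)

  # bit-identical re-run
  res2 <- run_pipeline(cc, sim$members, sim$dx, sim$rx, followup_dx = fup)
  expect_identical(res[c("cohort_report", "followup_report", "waterfall")],
                   res2[c("cohort_report", "followup_report", "waterfall")])
})

test_that("a cohort with no MHR members yields an all-zero follow-up report", {
  members <- member_tbl(c("z1", "z2"))
  dx <- dx_tbl("z1", "2016-02-01", "J0300")
  rx <- rx_tbl("z2", "2016-02-01", 5L)
  res <- run_pipeline(cohort_config(), members, dx, rx,
                      followup_dx = dx_tbl("z1", "2016-09-01", "J0300"))
  expect_equal(res$cohort_report$n_mhr, 0L)
  fr <- res$followup_report
  expect_equal(fr$n_mhr_retained, 0L)
  expect_equal(fr$n_new_pi, 0L)
  expect_equal(fr$n_concerning, 0L)
  expect_equal(fr$estimated_savings_usd, 0)
})
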