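rules <- window_rules()
wt <- tiny_weight_table()

test_that("episode counting respects the 30-day gap from episode start", {
  expect_equal(count_episodes(as.Date(c("2016-01-01", "2016-01-10", "2016-03-01")), 30), 2L)
  expect_equal(count_episodes(as.Date("2016-01-01") + seq(0, 240, by = 60), 30), 5L)
  expect_equal(count_episodes(as.Date(character()), 30), 0L)
  # gap measured from the episode's first claim, not the previous claim:
  # claims at 0, 20, 40 form two episodes (day 40 is 40 >= 30 after day 0)
  expect_equal(count_episodes(as.Date("2016-01-01") + c(0, 20, 40), 30), 2L)
  # order must not matter
  d <- as.Date("2016-01-01") + c(45, 0, 20, 90, 10)
  expect_equal(count_episodes(d, 30), count_episodes(sort(d), 30))
})

test_that("episodic allowances score only past the free episodes", {
  # otitis media: free 4, points from the 5th episode
  expect_equal(score_episodic(5L, 4L), 1L)
  expect_equal(score_episodic(4L, 4L), 0L)
  # sinusitis: free 2, points from the 3rd episode
  expect_equal(score_episodic(3L, 2L), 1L)
  expect_equal(score_episodic(2L, 2L), 0L)
  for (e in 0:10) {
    expect_equal(score_episodic(e, 4L), max(0L, e - 4L))
    expect_equal(score_episodic(e, 2L), max(0L, e - 2L))
  }
  expect_error(score_episodic(-1L, 4L), class = "pirisk_validation_error")
})

test_that("the continuous-antibiotic rule awards 3 points per 60-day course", {
  one <- function(supply) {
    score_pharmacy(rx_tbl("A1", "2016-02-01", supply), rules)
  }
  expect_equal(one(60L), 3L)
  expect_equal(one(59L), 0L)
  expect_equal(one(119L), 3L)  # floor(119/60) = 1 course
  expect_equal(one(120L), 6L)

  # two 60-day fills back to back form a 120-day run
  expect_equal(score_pharmacy(
    rx_tbl("A1", c("2016-01-01", "2016-03-01"), c(60L, 60L)), rules), 6L)
  # a 60-day gap breaks continuity: two 30-day runs score nothing
  expect_equal(score_pharmacy(
    rx_tbl("A1", c("2016-01-01", "2016-03-31"), c(30L, 30L)), rules), 0L)
  # a 5-day refill gap is bridged: 30 + 5 + 30 = 65-day run, one course
  expect_equal(score_pharmacy(
    rx_tbl("A1", c("2016-01-01", "2016-02-05"), c(30L, 30L)), rules), 3L)
  # an 8-day gap is not bridged under the 7-day slack
  expect_equal(score_pharmacy(
    rx_tbl("A1", c("2016-01-01", "2016-02-08"), c(30L, 30L)), rules), 0L)
  # non-antibiotic fills never score
  expect_equal(score_pharmacy(
    rx_tbl("A1", "2016-02-01", 90L, antibiotic = FALSE), rules), 0L)
  expect_equal(score_pharmacy(rx_tbl("A1", character(0), integer(0)), rules), 0L)
})

test_that("risk categories split at 8 and above 10", {
  expect_equal(categorize(10L, rules), "medium")
  expect_equal(categorize(11L, rules), "high")
  expect_equal(categorize(0L, rules), "low")
  expect_equal(categorize(0:12, rules),
               c(rep("low", 8), rep("medium", 3), rep("high", 2)))
  expect_error(categorize(-1L, rules), class = "pirisk_validation_error")
})

test_that("compute_score composes base, episodic and pharmacy points", {
  # 3 x weight-3 sepsis + 1 x weight-2 pneumonia = 11, high risk
  dx <- dx_tbl("A1", as.Date("2016-02-01") + 0:3,
               c("A403", "A403", "A403", "J18"))
  s <- compute_score("A1", dx, NULL, wt, rules)
  expect_equal(s$total, 11L)
  expect_equal(s$category, "high")
  expect_equal(s$base_points, 11L)
  expect_false(s$zero_score)
  expect_equal(sum(s$contributing_claims$points), s$total)

  # exactly 8 is medium (2+3+3)
  s8 <- compute_score("A1", dx_tbl("A1", as.Date("2016-02-01") + 0:2,
                                   c("J18", "A403", "A403")), NULL, wt, rules)
  expect_equal(s8$total, 8L)
  expect_equal(s8$category, "medium")

  # 7 is low (2+2+3)
  s7 <- compute_score("A1", dx_tbl("A1", as.Date("2016-02-01") + 0:2,
                                   c("J18", "J18", "A403")), NULL, wt, rules)
  expect_equal(s7$total, 7L)
  expect_equal(s7$category, "low")

  # no matching claims: 0, low, flagged as a true zero
  s0 <- compute_score("A1", dx_tbl("A1", "2016-02-01", "X999"), NULL, wt, rules)
  expect_equal(s0$total, 0L)
  expect_equal(s0$category, "low")
  expect_true(s0$zero_score)

  # 6 otitis episodes (free 4) plus one tonsillitis: 2 + 1
  dx_ot <- dx_tbl("A1", c(as.Date("2016-01-05") + 30 * (0:5), as.Date("2016-06-20")),
                  c(rep("H6690", 6), "J0300"))
  s_ot <- compute_score("A1", dx_ot, NULL, wt, rules)
  expect_equal(s_ot$otitis_points, 2L)
  expect_equal(s_ot$base_points, 1L)
  expect_equal(s_ot$total, 3L)
  expect_equal(sum(s_ot$contributing_claims$points), 3L)
})

test_that("claims outside the scoring window are refused unless filtered", {
  dx <- dx_tbl("A1", "2015-12-31", "A403")
  expect_error(compute_score("A1", dx, NULL, wt, rules),
               "window", class = "pirisk_validation_error")
  s <- compute_score("A1", dx, NULL, wt, rules, filter_to_window = TRUE)
  expect_equal(s$total, 0L)
  expect_error(compute_score("A1", dx_tbl("B2", "2016-02-01", "A403"),
                             NULL, wt, rules),
               "different member", class = "pirisk_validation_error")
})

test_that("score decomposition, permutation invariance and monotonicity hold", {
  set.seed(2016)
  for (i in 1:60) {
    cl <- random_claims(sample(0:25, 1), sample(0:6, 1), wt, rules)
    s <- compute_score("P1", cl$dx, cl$rx, wt, rules)
    expect_equal(s$total, s$base_points + s$otitis_points +
                   s$sinusitis_points + s$pharmacy_points)

    # permuting claim order changes nothing
    perm_dx <- cl$dx[sample.int(nrow(cl$dx)), ]
    perm_rx <- cl$rx[sample.int(nrow(cl$rx)), ]
    s2 <- compute_score("P1", perm_dx, perm_rx, wt, rules)
    expect_equal(s2[c("base_points", "otitis_points", "sinusitis_points",
                      "pharmacy_points", "total", "category")],
                 s[c("base_points", "otitis_points", "sinusitis_points",
                     "pharmacy_points", "total", "category")])

    # adding one claim never lowers the total
    extra <- random_claims(1, 1, wt, rules)
    s3 <- compute_score("P1", rbind(cl$dx, extra$dx), rbind(cl$rx, extra$rx),
                        wt, rules)
    expect_gte(s3$total, s$total)
  }
})

test_that("the vectorized cohort scorer agrees with the per-member scorer", {
  set.seed(99)
  members <- member_tbl(sprintf("P%02d", 1:20))
  all_dx <- list(); all_rx <- list()
  singles <- list()
  for (i in 1:20) {
    cl <- random_claims(sample(0:20, 1), sample(0:4, 1), wt, rules)
    cl$dx$member_id <- members$member_id[i]
    cl$rx$member_id <- members$member_id[i]
    all_dx[[i]] <- cl$dx; all_rx[[i]] <- cl$rx
    singles[[i]] <- compute_score(members$member_id[i], cl$dx, cl$rx, wt, rules)
  }
  scored <- score_cohort(members, dplyr::bind_rows(all_dx),
                         dplyr::bind_rows(all_rx), wt, rules)
  expect_equal(scored$total, vapply(singles, `[[`, 1L, "total"))
  expect_equal(scored$category, vapply(singles, `[[`, "", "category"))
  expect_equal(scored$pharmacy_points, vapply(singles, `[[`, 1L, "pharmacy_points"))
})

test_that("scoring rules serialize to YAML and back with exact field names", {
  path <- withr::local_tempfile(fileext = ".yaml")
  r <- scoring_rules(medium_min = 6L, episode_gap_days = 21L)
  write_scoring_rules(r, path)
  r2 <- read_scoring_rules(path)
  expect_equal(r2, r)
  keys <- names(yaml::read_yaml(path))
  expect_true(all(c("otitis_free_episodes", "antibiotic_course_days",
                    "medium_min", "high_min_exclusive", "window_start") %in% keys))
  expect_error(scoring_rules(medium_min = 0), class = "pirisk_validation_error")
  expect_error(scoring_rules(medium_min = 11, high_min_exclusive = 10),
               class = "pirisk_validation_error")
})
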