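test_that("code normalization strips dots, uppercases, and is idempotent", {
  expect_equal(normalize_code("d84.9"), "D849")
  expect_equal(normalize_code(" h66.90 "), "H6690")
  expect_equal(normalize_code("D849"), "D849")

  codes <- c("j01.90", "A40.3", " b59 ", "0.38.2", "z99")
  once <- normalize_code(codes)
  expect_equal(normalize_code(once), once)
  expect_equal(normalize_code(tolower(codes)), once)

  expect_error(normalize_code(""), class = "pirisk_validation_error")
  expect_error(normalize_code("   "), class = "pirisk_validation_error")
})

test_that("member roster reader accepts valid rows and accounts for rejects", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "member_id,birth_date,sex,ethnicity,enrolled_from,enrolled_to",
    "A1,2010-05-01,female,hispanic,2016-01-01,2017-07-01",
    "A2,2012-11-30,male,caucasian,2016-01-01,2016-07-01",
    "A3,2001-01-15,female,asian_pacific,2016-01-01,2017-07-01"
  ), path)
  m <- read_members(path)
  expect_equal(nrow(m), 3)
  expect_equal(nrow(rejects(m)), 0)
  expect_s3_class(m$birth_date, "Date")

  # reversed enrollment interval is rejected with a named reason
  writeLines(c(
    "member_id,birth_date,sex,ethnicity,enrolled_from,enrolled_to",
    "B1,2010-05-01,female,hispanic,2016-06-01,2016-01-01"
  ), path)
  m <- read_members(path)
  expect_equal(nrow(m), 0)
  expect_equal(rejects(m)$reason, "interval")

  # bad date, bad sex: one reject each, accounting holds
  writeLines(c(
    "member_id,birth_date,sex,ethnicity,enrolled_from,enrolled_to",
    "C1,not-a-date,female,hispanic,2016-01-01,2017-07-01",
    "C2,2010-05-01,robot,hispanic,2016-01-01,2017-07-01",
    "C3,2010-05-01,male,none_noted,2016-01-01,2017-07-01"
  ), path)
  m <- read_members(path)
  expect_equal(nrow(m) + nrow(rejects(m)), 3)
  expect_setequal(rejects(m)$reason, c("date", "sex"))
})

test_that("roster reader raises structured errors for schema problems", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("member_id,birth_date,sex", "A1,2010-05-01,female"), path)
  expect_error(read_members(path), "ethnicity", class = "pirisk_format_error")

  writeLines(c(
    "member_id,birth_date,sex,ethnicity,enrolled_from,enrolled_to",
    "A1,2010-05-01,female,hispanic,2016-01-01,2017-07-01",
    "A1,2011-02-01,male,caucasian,2016-01-01,2017-07-01"
  ), path)
  expect_error(read_members(path), "A1", class = "pirisk_validation_error")
})

test_that("claim readers normalize codes and reject invariant violations", {
  dxp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "member_id,service_date,icd_version,code",
    "A1,2016-02-01,10,J01.90",
    "A1,2016-02-15,10,d84.9",
    "A2,2016-03-01,11,J03",
    "A2,bad-date,10,J03",
    "A3,1960-01-01,9,486"
  ), dxp)
  dx <- read_dx_claims(dxp)
  expect_equal(dx$code, c("J0190", "D849"))
  expect_equal(nrow(dx) + nrow(rejects(dx)), 5)
  expect_setequal(rejects(dx)$reason, c("icd_version", "date", "date_range"))

  rxp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "member_id,fill_date,days_supply,is_antibiotic",
    "A1,2016-02-01,60,true",
    "A1,2016-03-01,0,true",
    "A2,2016-03-01,30,maybe"
  ), rxp)
  rx <- read_rx_claims(rxp)
  expect_equal(nrow(rx), 1)
  expect_setequal(rejects(rx)$reason, c("days_supply", "is_antibiotic"))

  # empty files with headers are fine
  writeLines("member_id,service_date,icd_version,code", dxp)
  writeLines("member_id,fill_date,days_supply,is_antibiotic", rxp)
  both <- read_claims(dxp, rxp)
  expect_equal(nrow(both$dx), 0)
  expect_equal(nrow(both$rx), 0)
})

test_that("a combined claim file splits on record_type", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "record_type,member_id,service_date,icd_version,code,fill_date,days_supply,is_antibiotic",
    "dx,A1,2016-02-01,10,J03,,,",
    "rx,A1,,,,2016-02-01,60,true"
  ), path)
  both <- read_claims(path)
  expect_equal(both$dx$code, "J03")
  expect_equal(both$rx$days_supply, 60L)

  writeLines("member_id,service_date,icd_version,code", path)
  expect_error(read_claims(path), "record_type", class = "pirisk_format_error")
})

test_that("weight table validation enforces weights, groups and uniqueness", {
  bad_weight <- tibble::tibble(code_prefix = "J03", icd_version = "10",
                               weight = 4L, episodic_group = "none",
                               label = "x")
  expect_error(weight_table(bad_weight, tibble::tibble(icd_version = "10",
                                                       code_prefix = "D80"),
                            default_weight_table()$concerning_groups),
               "weight", class = "pirisk_validation_error")

  dup <- tiny_weight_table()$entries[c(1, 1), ]
  expect_error(weight_table(dup, tiny_weight_table()$pi_codes,
                            tiny_weight_table()$concerning_groups),
               "duplicate", class = "pirisk_validation_error")

  episodic2 <- tibble::tibble(code_prefix = "H66", icd_version = "10",
                              weight = 2L, episodic_group = "otitis_media",
                              label = "x")
  expect_error(weight_table(episodic2, tiny_weight_table()$pi_codes,
                            tiny_weight_table()$concerning_groups),
               "weight 1", class = "pirisk_validation_error")

  # a PI prefix nested inside a scored prefix is refused
  clash <- tibble::tibble(icd_version = "10", code_prefix = "J031",
                          label = "not really PI")
  expect_error(weight_table(tiny_weight_table()$entries, clash,
                            tiny_weight_table()$concerning_groups),
               "overlaps", class = "pirisk_validation_error")
})

test_that("the default table carries the published anchor weights", {
  wt <- default_weight_table()
  lookup <- function(code, ver) {
    i <- pirisk:::match_longest_prefix(code, ver, wt$entries)
    wt$entries$weight[i]
  }
  expect_equal(lookup("A403", "10"), 3L)  # pneumococcal sepsis
  expect_equal(lookup("G001", "10"), 3L)  # bacterial meningitis
  expect_equal(lookup("B59", "10"), 3L)   # pneumocystis pneumonia
  expect_equal(lookup("J350", "10"), 1L)  # tonsillitis family
  expect_equal(lookup("J0190", "10"), 1L) # acute sinusitis
  expect_equal(lookup("H6690", "10"), 1L) # otitis media
  # PI family present for both versions
  expect_true(any(wt$pi_codes$code_prefix == "D849"))
  expect_true(any(wt$pi_codes$icd_version == "9" & wt$pi_codes$code_prefix == "279"))
})

test_that("longest-prefix matching is version-aware and prefers specific entries", {
  wt <- tiny_weight_table()
  m <- match_weights(dx_tbl("A1", rep("2016-02-01", 4),
                            c("A4031", "A401", "486", "Z991"),
                            version = c(10L, 10L, 9L, 9L)), wt)
  # A4031 hits the longer A403 entry, not A40
  expect_equal(m$matched_prefix, c("A403", "A40", "486", "Z99"))
  # ICD-9 claim never matches an ICD-10-only entry
  m9 <- match_weights(dx_tbl("A1", "2016-02-01", "J18", version = 9L), wt)
  expect_equal(m9$weight, 0L)
})

test_that("roster, claims and weight tables round-trip through files", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_members = 200, seed = 11)
  sim <- generate_cohort(cfg)

  write_members(sim$members, file.path(dir, "m.csv"))
  write_dx_claims(sim$dx, file.path(dir, "d.csv"))
  write_rx_claims(sim$rx, file.path(dir, "r.csv"))
  m2 <- read_members(file.path(dir, "m.csv"))
  d2 <- read_dx_claims(file.path(dir, "d.csv"))
  r2 <- read_rx_claims(file.path(dir, "r.csv"))
  expect_equal(nrow(rejects(m2)), 0)
  expect_equal(tibble::as_tibble(m2), sim$members, ignore_attr = TRUE)
  expect_equal(tibble::as_tibble(d2), sim$dx, ignore_attr = TRUE)
  expect_equal(tibble::as_tibble(r2), sim$rx, ignore_attr = TRUE)

  wt <- default_weight_table()
  write_weight_table(wt, file.path(dir, "w.csv"), file.path(dir, "pi.txt"),
                     file.path(dir, "cg.csv"))
  wt2 <- read_weight_table(file.path(dir, "w.csv"), file.path(dir, "pi.txt"),
                           file.path(dir, "cg.csv"))
  expect_equal(wt2$entries, wt$entries)
  expect_equal(wt2$pi_codes, wt$pi_codes)
  expect_equal(wt2$concerning_groups, wt$concerning_groups)
})
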