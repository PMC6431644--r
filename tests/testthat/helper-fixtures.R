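# Fixture builders shared across test files. Everything is built in code at
# test time; nothing is read from disk except files the tests write first.

dx_tbl <- function(member_id, dates, codes, version = 10L) {
  tibble::tibble(
    member_id = member_id,
    service_date = as.Date(dates),
    icd_version = as.integer(version),
    code = codes
  )
}

rx_tbl <- function(member_id, dates, supply, antibiotic = TRUE) {
  tibble::tibble(
    member_id = member_id,
    fill_date = as.Date(dates),
    days_supply = as.integer(supply),
    is_antibiotic = antibiotic
  )
}

member_tbl <- function(ids, birth = "2008-06-15", sex = "female",
                       ethnicity = "hispanic", from = "2016-01-01",
                       to = "2017-07-01") {
  tibble::tibble(
    member_id = ids,
    birth_date = as.Date(birth),
    sex = sex,
    ethnicity = ethnicity,
    enrolled_from = as.Date(from),
    enrolled_to = as.Date(to)
  )
}

# small table with one entry per structural feature: a mild code, an
# intermediate, a severe, both episodic groups, a version-"any" entry and
# nested prefixes for longest-prefix checks
tiny_weight_table <- function() {
  entries <- tibble::tribble(
    ~code_prefix, ~icd_version, ~weight, ~episodic_group, ~label,
    "J03",  "10", 1L, "none",         "tonsillitis",
    "J01",  "10", 1L, "sinusitis",    "acute sinusitis",
    "H66",  "10", 1L, "otitis_media", "otitis media",
    "J18",  "10", 2L, "none",         "pneumonia",
    "A40",  "10", 3L, "none",         "strep sepsis",
    "A403", "10", 3L, "none",         "pneumococcal sepsis",
    "486",  "9",  2L, "none",         "pneumonia (v9)",
    "Z99",  "any", 1L, "none",        "any-version mild"
  )
  pi_codes <- tibble::tribble(
    ~icd_version, ~code_prefix, ~label,
    "10", "D849", "Immunodeficiency NOS",
    "10", "D80",  "Antibody deficiency",
    "9",  "279",  "Immune disorder (v9)"
  )
  concerning <- tibble::tribble(
    ~group, ~icd_version, ~code_prefix, ~label,
    "cellulitis", "10", "L03", "Cellulitis",
    "abscess",    "10", "L02", "Abscess"
  )
  weight_table(entries, pi_codes, concerning)
}

window_rules <- function(...) {
  scoring_rules(window_start = as.Date("2016-01-01"),
                window_end = as.Date("2016-07-01"), ...)
}

# random member claim history for property tests; draws codes that mix
# matching prefixes, longer descendants of them, and junk
random_claims <- function(n_dx, n_rx, table, rules) {
  prefixes <- table$entries$code_prefix
  versions <- table$entries$icd_version
  i <- sample.int(length(prefixes), n_dx, replace = TRUE)
  suffix <- sample(c("", "0", "9", "12"), n_dx, replace = TRUE)
  code <- paste0(prefixes[i], suffix)
  junk <- sample.int(n_dx, size = floor(n_dx / 4))
  code[junk] <- paste0(sample(LETTERS, length(junk), TRUE), "99")
  ver <- ifelse(versions[i] == "any", sample(c("9", "10"), n_dx, TRUE), versions[i])
  ver[junk] <- sample(c("9", "10"), length(junk), TRUE)
  span <- as.integer(rules$window_end - rules$window_start)
  dx <- tibble::tibble(
    member_id = "P1",
    service_date = rules$window_start + sample.int(span, n_dx, TRUE) - 1L,
    icd_version = as.integer(ver),
    code = code
  )
  rx <- tibble::tibble(
    member_id = "P1",
    fill_date = rules$window_start + sample.int(span, n_rx, TRUE) - 1L,
    days_supply = sample(c(5L, 10L, 30L, 60L, 90L), n_rx, TRUE),
    is_antibiotic = sample(c(TRUE, TRUE, FALSE), n_rx, TRUE)
  )
  list(dx = dx, rx = rx)
}
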