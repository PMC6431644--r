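# Independent brute-force scorer used as the oracle for equivalence tests.
# Deliberately naive: per-claim loops over every table entry, episode
# counting by explicit scan, and the antibiotic rule via a day-coverage grid
# rather than interval merging. Shares no code with the package paths it
# checks.

oracle_match_entry <- function(code, version, table) {
  best <- NULL
  best_len <- -1L
  best_specific <- FALSE
  for (i in seq_len(nrow(table$entries))) {
    e <- table$entries[i, ]
    if (!(e$icd_version == "any" || e$icd_version == as.character(version))) next
    if (!startsWith(code, e$code_prefix)) next
    len <- nchar(e$code_prefix)
    specific <- e$icd_version != "any"
    if (len > best_len || (len == best_len && specific && !best_specific)) {
      best <- e
      best_len <- len
      best_specific <- specific
    }
  }
  best
}

oracle_count_episodes <- function(dates, gap_days) {
  dates <- sort(dates)
  count <- 0L
  ep_start <- NULL
  for (i in seq_along(dates)) {
    if (is.null(ep_start) || as.numeric(dates[i] - ep_start) >= gap_days) {
      count <- count + 1L
      ep_start <- dates[i]
    }
  }
  count
}

# day-grid route: mark covered days, chain runs whose gaps are within the
# refill slack, award points per completed course in each chain
oracle_pharmacy_points <- function(fill_dates, supplies, rules) {
  if (length(fill_dates) == 0) return(0L)
  days <- integer()
  for (i in seq_along(fill_dates)) {
    s <- as.integer(fill_dates[i])
    days <- c(days, s:(s + supplies[i] - 1L))
  }
  days <- sort(unique(days))
  breaks <- which(diff(days) > rules$antibiotic_merge_gap_days + 1L)
  starts <- days[c(1L, breaks + 1L)]
  ends <- days[c(breaks, length(days))] + 1L
  pts <- 0L
  for (j in seq_along(starts)) {
    pts <- pts + rules$antibiotic_course_points *
      (ends[j] - starts[j]) %/% rules$antibiotic_course_days
  }
  as.integer(pts)
}

oracle_score <- function(dx, rx, table, rules) {
  base <- 0L
  otitis_dates <- as.Date(character())
  sinus_dates <- as.Date(character())
  for (i in seq_len(nrow(dx))) {
    e <- oracle_match_entry(dx$code[i], dx$icd_version[i], table)
    if (is.null(e)) next
    if (e$episodic_group == "otitis_media") {
      otitis_dates <- c(otitis_dates, dx$service_date[i])
    } else if (e$episodic_group == "sinusitis") {
      sinus_dates <- c(sinus_dates, dx$service_date[i])
    } else {
      base <- base + e$weight
    }
  }
  otitis <- max(0L, oracle_count_episodes(otitis_dates, rules$episode_gap_days) -
                  rules$otitis_free_episodes)
  sinus <- max(0L, oracle_count_episodes(sinus_dates, rules$episode_gap_days) -
                 rules$sinusitis_free_episodes)
  abx <- rx[rx$is_antibiotic, , drop = FALSE]
  pharm <- oracle_pharmacy_points(abx$fill_date, abx$days_supply, rules)
  list(base = base, otitis = otitis, sinusitis = sinus, pharmacy = pharm,
       total = base + otitis + sinus + pharm)
}
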