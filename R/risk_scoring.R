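#' Scoring rules for the Risk Vital Sign
#'
#' Bundles every threshold of the point system. Defaults reproduce the
#' published algorithm: routine-childhood-infection allowances of 4 free
#' otitis media episodes and 2 free sinusitis episodes (points accrue from
#' the 5th and 3rd episode respectively), a 30-day inter-claim gap defining a
#' new episode, 3 points per 60 days of continuous antibiotic therapy
#' (supply intervals merged across refill gaps of at most 7 days), and the
#' category cut-offs: scores above 10 are high risk, 8-10 medium risk,
#' below 8 low risk. Members at 8 or more points form the medium-high-risk
#' (MHR) set.
#'
#' @param otitis_free_episodes otitis media episodes that score nothing
#'   (default 4; the 5th and subsequent each add 1 point).
#' @param sinusitis_free_episodes sinusitis episodes that score nothing
#'   (default 2; the 3rd and subsequent each add 1 point).
#' @param episode_gap_days days since the start of the current episode after
#'   which a claim opens a new episode (default 30).
#' @param antibiotic_course_days length in days of one scoring antibiotic
#'   course (default 60).
#' @param antibiotic_course_points points per completed course (default 3).
#' @param antibiotic_merge_gap_days refill slack: supply intervals separated
#'   by at most this many days count as continuous therapy (default 7).
#' @param medium_min lowest medium-risk total, also the MHR threshold
#'   (default 8).
#' @param high_min_exclusive highest medium-risk total; anything above is
#'   high risk (default 10).
#' @param window_start,window_end analysis window, half-open
#'   `[window_start, window_end)`.
#' @return an object of class `pirisk_rules`.
#' @export
scoring_rules <- function(otitis_free_episodes = 4L,
                          sinusitis_free_episodes = 2L,
                          episode_gap_days = 30L,
                          antibiotic_course_days = 60L,
                          antibiotic_course_points = 3L,
                          antibiotic_merge_gap_days = 7L,
                          medium_min = 8L,
                          high_min_exclusive = 10L,
                          window_start = as.Date("2016-01-01"),
                          window_end = as.Date("2016-07-01")) {
  rules <- list(
    otitis_free_episodes = as.integer(otitis_free_episodes),
    sinusitis_free_episodes = as.integer(sinusitis_free_episodes),
    episode_gap_days = as.integer(episode_gap_days),
    antibiotic_course_days = as.integer(antibiotic_course_days),
    antibiotic_course_points = as.integer(antibiotic_course_points),
    antibiotic_merge_gap_days = as.integer(antibiotic_merge_gap_days),
    medium_min = as.integer(medium_min),
    high_min_exclusive = as.integer(high_min_exclusive),
    window_start = as.Date(window_start),
    window_end = as.Date(window_end)
  )
  day_fields <- c("episode_gap_days", "antibiotic_course_days",
                  "antibiotic_course_points", "antibiotic_merge_gap_days")
  if (any(vapply(rules[day_fields], function(x) is.na(x) || x < 1L, TRUE))) {
    abort_validation("scoring_rules: all day counts and points must be positive")
  }
  if (rules$otitis_free_episodes < 0 || rules$sinusitis_free_episodes < 0) {
    abort_validation("scoring_rules: free episode counts must be non-negative")
  }
  if (!(rules$medium_min > 0 && rules$medium_min <= rules$high_min_exclusive)) {
    abort_validation("scoring_rules: need 0 < medium_min <= high_min_exclusive")
  }
  if (!(rules$window_start < rules$window_end)) {
    abort_validation("scoring_rules: window_start must precede window_end")
  }
  structure(rules, class = "pirisk_rules")
}

#' @export
print.pirisk_rules <- function(x, ...) {
  cat("<pirisk_rules>\n")
  cat(sprintf("  window [%s, %s)\n", x$window_start, x$window_end))
  cat(sprintf("  episodes: gap %dd; free otitis %d, free sinusitis %d\n",
              x$episode_gap_days, x$otitis_free_episodes, x$sinusitis_free_episodes))
  cat(sprintf("  antibiotics: %d pts per %dd course, merge gap %dd\n",
              x$antibiotic_course_points, x$antibiotic_course_days,
              x$antibiotic_merge_gap_days))
  cat(sprintf("  categories: low < %d <= medium <= %d < high\n",
              x$medium_min, x$high_min_exclusive))
  invisible(x)
}

#' Serialize scoring rules to YAML
#'
#' Key names match the [scoring_rules()] argument names exactly, so a config
#' file can be hand-edited and read back with [read_scoring_rules()].
#'
#' @param rules a `pirisk_rules` object.
#' @param path destination YAML file.
#' @export
write_scoring_rules <- function(rules, path) {
  stopifnot(inherits(rules, "pirisk_rules"))
  out <- unclass(rules)
  out$window_start <- format(out$window_start)
  out$window_end <- format(out$window_end)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_scoring_rules
#' @export
read_scoring_rules <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(scoring_rules))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort_format(sprintf("%s: unknown rule key(s): %s", basename(path),
                         paste(unknown, collapse = ", ")))
  }
  do.call(scoring_rules, vals)
}

# Assign a 1-based episode index to each claim date (any order). A claim
# opens a new episode iff it falls >= gap_days after the first claim of the
# current episode. Returns indices aligned with the input order.
episode_index <- function(dates, gap_days) {
  n <- length(dates)
  if (n == 0) return(integer())
  ord <- order(dates)
  d <- as.numeric(dates[ord])
  idx <- integer(n)
  ep <- 1L
  ep_start <- d[1]
  idx[1] <- 1L
  for (i in seq_len(n)[-1]) {
    if (d[i] - ep_start >= gap_days) {
      ep <- ep + 1L
      ep_start <- d[i]
    }
    idx[i] <- ep
  }
  out <- integer(n)
  out[ord] <- idx
  out
}

#' Count infection episodes from claim dates
#'
#' Collapses claims of one episodic group (otitis media or sinusitis) for one
#' member into clinically distinct episodes: claims within `gap_days` of the
#' current episode's first claim belong to that episode; a claim `gap_days`
#' or more after the episode start opens a new one.
#'
#' @param dates claim service dates (Date vector, any order).
#' @param gap_days inter-claim gap opening a new episode.
#' @return integer episode count (0 for empty input).
#' @examples
#' count_episodes(as.Date(c("2016-01-01", "2016-01-10", "2016-03-01")), 30) # 2
#' @export
count_episodes <- function(dates, gap_days) {
  stopifnot(gap_days >= 1)
  if (length(dates) == 0) return(0L)
  max(episode_index(dates, gap_days))
}

#' Points for recurrent-infection episodes
#'
#' The routine-childhood-infection allowance: the first `free_episodes`
#' episodes score nothing, every further episode scores 1 point.
#'
#' @param episodes episode count (from [count_episodes()]).
#' @param free_episodes allowance (4 for otitis media, 2 for sinusitis).
#' @return integer points, `max(0, episodes - free_episodes)`.
#' @export
score_episodic <- function(episodes, free_episodes) {
  if (any(episodes < 0) || any(free_episodes < 0)) {
    abort_validation("score_episodic: counts must be non-negative")
  }
  as.integer(pmax(0, episodes - free_episodes))
}

# Merge antibiotic supply intervals [fill, fill + days_supply) into
# continuous-therapy runs, bridging gaps of at most merge_gap days.
# Returns a tibble of runs with start/end (numeric days) and length.
merge_supply_runs <- function(fill_dates, days_supply, merge_gap) {
  stopifnot(length(fill_dates) == length(days_supply))
  if (length(fill_dates) == 0) {
    return(tibble::tibble(start = numeric(), end = numeric(), length = numeric()))
  }
  ord <- order(fill_dates)
  s <- as.numeric(fill_dates[ord])
  e <- s + as.numeric(days_supply[ord])
  run_s <- s[1]
  run_e <- e[1]
  starts <- ends <- numeric()
  for (i in seq_along(s)[-1]) {
    if (s[i] - run_e <= merge_gap) {
      run_e <- max(run_e, e[i])
    } else {
      starts <- c(starts, run_s); ends <- c(ends, run_e)
      run_s <- s[i]; run_e <- e[i]
    }
  }
  starts <- c(starts, run_s); ends <- c(ends, run_e)
  tibble::tibble(start = starts, end = ends, length = ends - starts)
}

#' Points from continuous antibiotic therapy
#'
#' Pharmacy claims contribute only through prolonged continuous antibiotic
#' use: supply intervals `[fill_date, fill_date + days_supply)` are merged
#' into runs (gaps of at most `antibiotic_merge_gap_days` count as
#' continuous), and each run awards `antibiotic_course_points` per completed
#' `antibiotic_course_days` (default: 3 points per 60-day course, so a
#' 59-day run scores 0 and a 119-day run scores 3).
#'
#' @param fills pharmacy-claim data frame (`fill_date`, `days_supply`,
#'   optionally `is_antibiotic`); non-antibiotic rows are ignored.
#' @param rules a [scoring_rules()] object.
#' @return integer points.
#' @export
score_pharmacy <- function(fills, rules) {
  stopifnot(inherits(rules, "pirisk_rules"))
  if (is.null(fills) || nrow(fills) == 0) return(0L)
  if ("is_antibiotic" %in% names(fills)) fills <- fills[fills$is_antibiotic, ]
  score_pharmacy_dates(fills$fill_date, fills$days_supply, rules)
}

score_pharmacy_dates <- function(fill_dates, days_supply, rules) {
  if (length(fill_dates) == 0) return(0L)
  runs <- merge_supply_runs(fill_dates, days_supply,
                            rules$antibiotic_merge_gap_days)
  as.integer(rules$antibiotic_course_points *
               sum(floor(runs$length / rules$antibiotic_course_days)))
}

#' Risk category for a point total
#'
#' @param total integer score(s), non-negative.
#' @param rules a [scoring_rules()] object.
#' @return character vector in `c("low", "medium", "high")`: high above
#'   `high_min_exclusive`, medium from `medium_min` to `high_min_exclusive`,
#'   low below (a score of 0 is reported as low; see `zero_score` in
#'   [compute_score()]).
#' @export
categorize <- function(total, rules) {
  stopifnot(inherits(rules, "pirisk_rules"))
  if (any(is.na(total)) || any(total < 0)) {
    abort_validation("categorize: totals must be non-negative")
  }
  ifelse(total > rules$high_min_exclusive, "high",
         ifelse(total >= rules$medium_min, "medium", "low"))
}

check_claims_in_window <- function(dates, rules, what) {
  out <- dates >= rules$window_start & dates < rules$window_end
  if (!all(out)) {
    abort_validation(sprintf(
      "%s: %d claim(s) outside scoring window [%s, %s); pre-filter or pass filter_to_window = TRUE",
      what, sum(!out), rules$window_start, rules$window_end))
  }
  invisible(TRUE)
}

#' Compute one member's Risk Vital Sign
#'
#' Enumerates the member's weighted infection claims within the scoring
#' window: non-episodic matched claims each contribute their code weight
#' (every matching claim scores; there is no per-code cap), otitis media and
#' sinusitis claims are collapsed into episodes and scored past their free
#' allowances, and antibiotic fills are scored by the continuous-therapy
#' rule. Claims matching no weight-table entry contribute nothing.
#'
#' @param member_id the member being scored; claims carrying a different
#'   `member_id` are an error.
#' @param dx_claims,rx_claims the member's diagnosis and pharmacy claims.
#' @param table a [weight_table()].
#' @param rules a [scoring_rules()].
#' @param filter_to_window if `FALSE` (default), claims outside the scoring
#'   window raise a validation error; if `TRUE` they are dropped first.
#' @return a `pirisk_score` list: `member_id`, `base_points`,
#'   `otitis_points`, `sinusitis_points`, `pharmacy_points`, `total`,
#'   `category`, `zero_score`, and `contributing_claims` (a tibble mapping
#'   each scoring claim to the points it was awarded; episodic points are
#'   attributed to the first claim of each scoring episode).
#' @export
compute_score <- function(member_id, dx_claims, rx_claims, table, rules,
                          filter_to_window = FALSE) {
  stopifnot(inherits(table, "pirisk_weight_table"), inherits(rules, "pirisk_rules"))
  dx_claims <- dx_claims %||%
    tibble::tibble(member_id = character(), service_date = as.Date(character()),
                   icd_version = integer(), code = character())
  rx_claims <- rx_claims %||%
    tibble::tibble(member_id = character(), fill_date = as.Date(character()),
                   days_supply = integer(), is_antibiotic = logical())
  if ("member_id" %in% names(dx_claims) &&
      any(dx_claims$member_id != member_id)) {
    abort_validation("compute_score: diagnosis claims from a different member")
  }
  if ("member_id" %in% names(rx_claims) &&
      any(rx_claims$member_id != member_id)) {
    abort_validation("compute_score: pharmacy claims from a different member")
  }
  if (filter_to_window) {
    dx_claims <- dx_claims[dx_claims$service_date >= rules$window_start &
                             dx_claims$service_date < rules$window_end, ]
    rx_claims <- rx_claims[rx_claims$fill_date >= rules$window_start &
                             rx_claims$fill_date < rules$window_end, ]
  } else {
    if (nrow(dx_claims) > 0)
      check_claims_in_window(dx_claims$service_date, rules, "compute_score (dx)")
    if (nrow(rx_claims) > 0)
      check_claims_in_window(rx_claims$fill_date, rules, "compute_score (rx)")
  }

  matched <- match_weights(dx_claims, table)
  base_rows <- matched[matched$episodic_group == "none" & matched$weight > 0, ]
  base_points <- as.integer(sum(base_rows$weight))

  contrib <- tibble::tibble(
    source = rep("dx", nrow(base_rows)),
    date = base_rows$service_date,
    code = base_rows$code,
    points = as.integer(base_rows$weight)
  )

  episodic_points <- function(group, free) {
    rows <- matched[matched$episodic_group == group, ]
    if (nrow(rows) == 0) return(0L)
    idx <- episode_index(rows$service_date, rules$episode_gap_days)
    pts <- score_episodic(max(idx), free)
    if (pts > 0) {
      # attribute 1 point to the first claim of each episode past the allowance
      scoring_eps <- sort(unique(idx))[(free + 1):max(idx)]
      firsts <- vapply(scoring_eps, function(e) {
        which(idx == e)[which.min(rows$service_date[idx == e])]
      }, 1L)
      contrib <<- dplyr::bind_rows(contrib, tibble::tibble(
        source = "dx", date = rows$service_date[firsts],
        code = rows$code[firsts], points = 1L))
    }
    pts
  }
  otitis_points <- episodic_points("otitis_media", rules$otitis_free_episodes)
  sinusitis_points <- episodic_points("sinusitis", rules$sinusitis_free_episodes)

  abx <- rx_claims[rx_claims$is_antibiotic, , drop = FALSE]
  pharmacy_points <- score_pharmacy(abx, rules)
  if (pharmacy_points > 0) {
    runs <- merge_supply_runs(abx$fill_date, abx$days_supply,
                              rules$antibiotic_merge_gap_days)
    run_pts <- rules$antibiotic_course_points *
      floor(runs$length / rules$antibiotic_course_days)
    keep <- run_pts > 0
    contrib <- dplyr::bind_rows(contrib, tibble::tibble(
      source = "rx", date = as.Date(runs$start[keep], origin = "1970-01-01"),
      code = NA_character_, points = as.integer(run_pts[keep])))
  }

  total <- base_points + otitis_points + sinusitis_points + pharmacy_points
  structure(list(
    member_id = member_id,
    base_points = base_points,
    otitis_points = otitis_points,
    sinusitis_points = sinusitis_points,
    pharmacy_points = pharmacy_points,
    total = as.integer(total),
    category = categorize(total, rules),
    zero_score = total == 0L,
    contributing_claims = contrib
  ), class = "pirisk_score")
}

#' @export
print.pirisk_score <- function(x, ...) {
  cat(sprintf("<pirisk_score> member %s: total %d (%s)\n",
              x$member_id, x$total, x$category))
  cat(sprintf("  base %d + otitis %d + sinusitis %d + pharmacy %d\n",
              x$base_points, x$otitis_points, x$sinusitis_points,
              x$pharmacy_points))
  invisible(x)
}

#' Score every member of a cohort
#'
#' Vectorized equivalent of [compute_score()] over a roster: members with no
#' claims score 0 (low risk). Claims are filtered to the scoring window.
#'
#' @param members roster data frame (only `member_id` is required).
#' @param dx_claims,rx_claims claim data frames for the whole cohort.
#' @param table a [weight_table()].
#' @param rules a [scoring_rules()].
#' @return tibble with one row per member: `member_id`, `base_points`,
#'   `otitis_points`, `sinusitis_points`, `pharmacy_points`, `total`,
#'   `category`, `zero_score`.
#' @export
score_cohort <- function(members, dx_claims, rx_claims, table, rules) {
  stopifnot(inherits(table, "pirisk_weight_table"), inherits(rules, "pirisk_rules"))
  ids <- members$member_id
  dx <- dx_claims[dx_claims$member_id %in% ids &
                    dx_claims$service_date >= rules$window_start &
                    dx_claims$service_date < rules$window_end, ]
  rx <- rx_claims[rx_claims$member_id %in% ids &
                    rx_claims$is_antibiotic &
                    rx_claims$fill_date >= rules$window_start &
                    rx_claims$fill_date < rules$window_end, ]
  matched <- match_weights(dx, table)

  base <- matched |>
    dplyr::filter(.data$episodic_group == "none", .data$weight > 0) |>
    dplyr::group_by(.data$member_id) |>
    dplyr::summarise(base_points = sum(.data$weight), .groups = "drop")

  episodic <- matched |>
    dplyr::filter(.data$episodic_group != "none") |>
    dplyr::group_by(.data$member_id, .data$episodic_group) |>
    dplyr::summarise(
      episodes = count_episodes(.data$service_date, rules$episode_gap_days),
      .groups = "drop"
    ) |>
    dplyr::mutate(points = score_episodic(
      .data$episodes,
      ifelse(.data$episodic_group == "otitis_media",
             rules$otitis_free_episodes, rules$sinusitis_free_episodes)
    )) |>
    tidyr::pivot_wider(id_cols = "member_id", names_from = "episodic_group",
                       values_from = "points", values_fill = 0L)

  pharmacy <- rx |>
    dplyr::group_by(.data$member_id) |>
    dplyr::summarise(
      pharmacy_points = score_pharmacy_dates(.data$fill_date,
                                             .data$days_supply, rules),
      .groups = "drop"
    )

  out <- tibble::tibble(member_id = ids) |>
    dplyr::left_join(base, by = "member_id") |>
    dplyr::left_join(pharmacy, by = "member_id")
  for (col in c("otitis_media", "sinusitis")) {
    out[[col]] <- if (col %in% names(episodic)) {
      episodic[[col]][match(out$member_id, episodic$member_id)]
    } else NA_integer_
  }
  out |>
    dplyr::mutate(
      base_points = as.integer(dplyr::coalesce(.data$base_points, 0L)),
      otitis_points = as.integer(dplyr::coalesce(.data$otitis_media, 0L)),
      sinusitis_points = as.integer(dplyr::coalesce(.data$sinusitis, 0L)),
      pharmacy_points = as.integer(dplyr::coalesce(.data$pharmacy_points, 0L)),
      total = .data$base_points + .data$otitis_points +
        .data$sinusitis_points + .data$pharmacy_points,
      category = categorize(.data$total, rules),
      zero_score = .data$total == 0L
    ) |>
    dplyr::select("member_id", "base_points", "otitis_points",
                  "sinusitis_points", "pharmacy_points", "total", "category",
                  "zero_score")
}

#' Export a score table as scores.csv
#'
#' @param scores tibble from [score_cohort()].
#' @param path destination CSV.
#' @export
write_scores <- function(scores, path) {
  readr::write_csv(scores[, c("member_id", "base_points", "otitis_points",
                              "sinusitis_points", "pharmacy_points", "total",
                              "category")], path)
  invisible(path)
}
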