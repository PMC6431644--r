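#' Configuration for the synthetic-claims generator
#'
#' Describes a synthetic pediatric health-plan population with the
#' statistical structure the screening pipeline assumes: demographic
#' marginals matching the published main cohort, Poisson background
#' incidence of mild/intermediate/severe infection codes, otitis media and
#' sinusitis episode bursts, occasional long antibiotic courses, and planted
#' risk phenotypes (prior-PI members who must be excluded, and medium-high-
#' risk members guaranteed to score at or above the MHR threshold, a
#' configurable fraction of whom later convert to a coded PI or a concerning
#' diagnosis). Defaults are anchored to the published cohort: 1.2% of
#' members MHR, 3.8% of the focused MHR group converting to PI and 5.3% to a
#' concerning diagnosis, and a focused-MHR retention of 1068/2188.
#'
#' @param n_members cohort size.
#' @param seed integer seed; mandatory, every draw derives from it.
#' @param demographics list of named probability vectors `ethnicity`, `sex`,
#'   `age_band`; defaults are the published main-cohort proportions.
#' @param background_rates mean claims per member per baseline window for
#'   weight-1/2/3 codes, named `mild`, `intermediate`, `severe`.
#' @param otitis_burst,sinusitis_burst lists `list(prob, episodes, weights)`:
#'   probability a member has an episodic burst and the distribution of
#'   episode counts.
#' @param long_antibiotic list `list(prob, days, weights)`: probability of a
#'   long antibiotic course and the days-supply distribution.
#' @param planted_mhr_fraction fraction of members planted with a claim
#'   bundle guaranteeing an MHR score (default 0.012).
#' @param planted_prior_pi_fraction fraction planted with a baseline PI code
#'   (default 0.002); these members must be excluded by the pipeline.
#' @param followup_pi_conversion probability a planted-MHR member receives a
#'   coded PI diagnosis at follow-up (default 0.038).
#' @param followup_concerning_conversion probability of a concerning
#'   diagnosis instead (default 0.053); the two conversions are exclusive.
#' @param followup_retention probability an MHR member remains enrolled
#'   through the follow-up window (default 1068/2188).
#' @param episode_gap_days spacing between generated burst episodes; equals
#'   the scoring episode gap so planted episode counts are unambiguous.
#' @param baseline_start,baseline_end,followup_start,followup_end windows.
#' @param dispersion optional negative-binomial size parameter for
#'   over-dispersed background counts; `NULL` (default) keeps Poisson.
#' @return an object of class `pirisk_sim_config`.
#' @export
sim_config <- function(n_members,
                       seed,
                       demographics = default_demographics(),
                       background_rates = c(mild = 1.5, intermediate = 0.2,
                                            severe = 0.02),
                       otitis_burst = list(prob = 0.02, episodes = 2:6,
                                           weights = NULL),
                       sinusitis_burst = list(prob = 0.02, episodes = 1:4,
                                              weights = NULL),
                       long_antibiotic = list(prob = 0.004,
                                              days = c(30L, 60L, 90L, 120L),
                                              weights = c(0.4, 0.3, 0.2, 0.1)),
                       planted_mhr_fraction = 0.012,
                       planted_prior_pi_fraction = 0.002,
                       followup_pi_conversion = 0.038,
                       followup_concerning_conversion = 0.053,
                       followup_retention = 1068 / 2188,
                       episode_gap_days = 30L,
                       baseline_start = as.Date("2016-01-01"),
                       baseline_end = as.Date("2016-07-01"),
                       followup_start = as.Date("2016-07-01"),
                       followup_end = as.Date("2017-07-01"),
                       dispersion = NULL) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    abort_validation("sim_config: seed is mandatory")
  }
  probs <- c(planted_mhr_fraction, planted_prior_pi_fraction,
             followup_pi_conversion, followup_concerning_conversion,
             followup_retention,
             otitis_burst$prob, sinusitis_burst$prob, long_antibiotic$prob)
  if (any(probs < 0 | probs > 1)) {
    abort_validation("sim_config: probabilities must lie in [0, 1]")
  }
  if (planted_mhr_fraction + planted_prior_pi_fraction > 1) {
    abort_validation("sim_config: planted fractions sum above 1")
  }
  if (followup_pi_conversion + followup_concerning_conversion > 1) {
    abort_validation("sim_config: follow-up conversion probabilities sum above 1")
  }
  if (any(background_rates < 0)) {
    abort_validation("sim_config: background rates must be non-negative")
  }
  demographics <- lapply(demographics, function(p) p / sum(p))
  structure(list(
    n_members = as.integer(n_members), seed = as.integer(seed),
    demographics = demographics,
    background_rates = background_rates,
    otitis_burst = otitis_burst, sinusitis_burst = sinusitis_burst,
    long_antibiotic = long_antibiotic,
    planted_mhr_fraction = planted_mhr_fraction,
    planted_prior_pi_fraction = planted_prior_pi_fraction,
    followup_pi_conversion = followup_pi_conversion,
    followup_concerning_conversion = followup_concerning_conversion,
    followup_retention = followup_retention,
    episode_gap_days = as.integer(episode_gap_days),
    baseline_start = as.Date(baseline_start),
    baseline_end = as.Date(baseline_end),
    followup_start = as.Date(followup_start),
    followup_end = as.Date(followup_end),
    dispersion = dispersion
  ), class = "pirisk_sim_config")
}

#' Published main-cohort demographic marginals
#'
#' Stratum proportions of the 185,892-member pediatric health-plan cohort
#' the score was deployed on, used as generator defaults.
#'
#' @return list of named probability vectors `ethnicity`, `sex`, `age_band`.
#' @export
default_demographics <- function() {
  counts <- reference_counts()
  list(
    ethnicity = counts$main_ethnicity / sum(counts$main_ethnicity),
    sex = counts$main_sex / sum(counts$main_sex),
    age_band = counts$main_age / sum(counts$main_age)
  )
}

# PI labels and representative codes with the published follow-up code
# distribution (46 coded conditions)
pi_label_distribution <- function() {
  tibble::tibble(
    label = c("Immunodeficiency NOS", "Selective IgA deficiency",
              "Selective IgM deficiency", "IgG subclass deficiency",
              "Common variable immunodeficiency",
              "Primary immunodeficiency associated with other disorder"),
    code = c("D849", "D802", "D804", "D803", "D839", "D821"),
    n = c(37L, 3L, 3L, 1L, 1L, 1L)
  )
}

# concerning-diagnosis groups with the published code distribution (59 codes)
concerning_group_distribution <- function() {
  tibble::tibble(
    group = c("cellulitis", "abscess", "recurrent_otitis_media",
              "recurrent_sinusitis", "bacterial_pneumonia", "osteomyelitis",
              "mastoiditis", "pulmonary_tuberculosis", "lymphadenitis",
              "atypical_mycobacterial"),
    n = c(18L, 14L, 11L, 5L, 5L, 2L, 1L, 1L, 1L, 1L)
  )
}

# code pools for background claims: all weighted entries except those inside
# a concerning-diagnosis family (PI families are disjoint by construction),
# so follow-up tallies reflect planted conversions only. Episodic codes that
# survive the filter stay in the mild pool: in a pediatric claims stream the
# modal mild codes are otitis/sinusitis codes, and most of them score
# nothing thanks to the free-episode allowance.
background_pools <- function(table) {
  e <- table$entries
  conc_idx <- match_longest_prefix(e$code_prefix,
                                   ifelse(e$icd_version == "any", "10",
                                          e$icd_version),
                                   table$concerning_groups)
  e <- e[is.na(conc_idx), ]
  split(e, e$weight)
}

# representative claim code for a concerning group (ICD-10 prefix preferred)
concerning_code_for <- function(group, table) {
  rows <- table$concerning_groups[table$concerning_groups$group == group, ]
  if (nrow(rows) == 0) {
    abort_validation(sprintf(
      "concerning group '%s' is not defined in the weight table", group))
  }
  i <- which(rows$icd_version == "10")[1]
  if (is.na(i)) i <- 1L
  list(code = rows$code_prefix[i], version = rows$icd_version[i])
}

empty_dx <- function() {
  tibble::tibble(member_id = character(), service_date = as.Date(character()),
                 icd_version = integer(), code = character())
}

shift_years <- function(dates, k) {
  lt <- as.POSIXlt(dates)
  lt$year <- lt$year + k
  out <- as.Date(lt)
  # Feb 29 in a non-leap target year -> March 1
  bad <- is.na(out)
  if (any(bad)) {
    lt2 <- as.POSIXlt(dates[bad]); lt2$year <- lt2$year + k
    lt2$mon <- 2L; lt2$mday <- 1L
    out[bad] <- as.Date(lt2)
  }
  out
}

sample_dates <- function(n, from, to_exclusive) {
  span <- as.integer(to_exclusive - from)
  from + sample.int(span, n, replace = TRUE) - 1L
}

draw_counts <- function(n, rate, dispersion) {
  if (is.null(dispersion)) stats::rpois(n, rate)
  else stats::rnbinom(n, size = dispersion, mu = rate)
}

sample_from <- function(x, n, weights = NULL) {
  x[sample.int(length(x), n, replace = TRUE, prob = weights)]
}

#' Generate a synthetic baseline cohort
#'
#' Draws a member roster, baseline diagnosis and pharmacy claims, and a
#' ground-truth file from a [sim_config()]. Planted-MHR members receive
#' three severe (weight-3) codes, guaranteeing a score of at least 9 and
#' hence membership in the MHR set; planted prior-PI members receive a
#' baseline PI-family claim and must be removed by the exclusion stage.
#' Follow-up conversion outcomes (PI label or concerning group) are
#' pre-drawn here and recorded in the truth file; [generate_followup()]
#' materializes them as claims. Fully reproducible: the same config gives
#' byte-identical files.
#'
#' @param config a [sim_config()].
#' @param table a [weight_table()] supplying the code pools (default:
#'   [default_weight_table()]).
#' @param out_dir optional directory; when given, writes `members.csv`,
#'   `dx_claims.csv`, `rx_claims.csv`, `truth.csv`.
#' @return list with tibbles `members`, `dx`, `rx`, `truth`.
#' @export
generate_cohort <- function(config, table = default_weight_table(),
                            out_dir = NULL) {
  stopifnot(inherits(config, "pirisk_sim_config"))
  set.seed(config$seed)
  n <- config$n_members
  ws <- config$baseline_start
  we <- config$baseline_end

  ids <- sprintf("M%06d", seq_len(n))

  # exclusive planted roles
  u <- stats::runif(n)
  role <- ifelse(u < config$planted_prior_pi_fraction, "prior_pi",
                 ifelse(u < config$planted_prior_pi_fraction +
                          config$planted_mhr_fraction, "mhr", "background"))

  eth <- sample_from(names(config$demographics$ethnicity), n,
                     config$demographics$ethnicity)
  sex <- sample_from(names(config$demographics$sex), n,
                     config$demographics$sex)
  band <- sample_from(names(config$demographics$age_band), n,
                      config$demographics$age_band)
  band_row <- match(band, AGE_BANDS$band)
  age <- AGE_BANDS$lo[band_row] +
    floor(stats::runif(n) * (AGE_BANDS$hi[band_row] - AGE_BANDS$lo[band_row] + 1))
  # birth date uniform over the interval giving exactly `age` completed years
  # at the baseline start
  lo <- shift_years(rep(ws, n), -(age + 1L)) + 1L
  hi <- shift_years(rep(ws, n), -age)
  birth <- lo + floor(stats::runif(n) * (as.integer(hi - lo) + 1L))

  retained <- stats::runif(n) < config$followup_retention
  members <- tibble::tibble(
    member_id = ids,
    birth_date = birth,
    sex = sex,
    ethnicity = eth,
    enrolled_from = ws,
    enrolled_to = dplyr::if_else(retained, config$followup_end, we)
  )

  pools <- background_pools(table)
  dx_parts <- list()

  # background claims per severity tier
  rates <- config$background_rates
  for (tier in c("1", "2", "3")) {
    rate <- rates[[c("1" = "mild", "2" = "intermediate", "3" = "severe")[tier]]]
    counts <- draw_counts(n, rate, config$dispersion)
    total <- sum(counts)
    if (total == 0) next
    pool <- pools[[tier]]
    pick <- sample.int(nrow(pool), total, replace = TRUE)
    dx_parts[[paste0("bg", tier)]] <- tibble::tibble(
      member_id = rep(ids, counts),
      service_date = sample_dates(total, ws, we),
      icd_version = as.integer(pool$icd_version[pick]),
      code = pool$code_prefix[pick]
    )
  }

  # episodic bursts: episodes spaced exactly episode_gap_days apart so the
  # planted episode count is unambiguous under the scoring gap rule
  burst_claims <- function(burst, group) {
    has <- stats::runif(n) < burst$prob
    k <- integer(n)
    k[has] <- sample_from(burst$episodes, sum(has), burst$weights)
    idx <- which(k > 0)
    if (length(idx) == 0) return(NULL)
    gap <- config$episode_gap_days
    pool <- table$entries[table$entries$episodic_group == group, ]
    span_last <- as.integer(we - ws) - (k[idx] - 1L) * gap
    if (any(span_last < 1L)) {
      abort_validation(sprintf(
        "generate_cohort: %s burst of %d episodes does not fit the window",
        group, max(k[idx])))
    }
    start <- ws + vapply(span_last, function(s) sample.int(s, 1L) - 1L, 1L)
    rows <- rep(seq_along(idx), k[idx])
    ep <- unlist(lapply(k[idx], seq_len)) - 1L
    pick <- sample.int(nrow(pool), length(rows), replace = TRUE)
    tibble::tibble(
      member_id = ids[idx][rows],
      service_date = start[rows] + ep * gap,
      icd_version = as.integer(pool$icd_version[pick]),
      code = pool$code_prefix[pick]
    )
  }
  dx_parts$otitis <- burst_claims(config$otitis_burst, "otitis_media")
  dx_parts$sinusitis <- burst_claims(config$sinusitis_burst, "sinusitis")

  # planted MHR bundle: three severe codes guarantee total >= 9 >= MHR cut
  mhr_idx <- which(role == "mhr")
  if (length(mhr_idx) > 0) {
    sev <- pools[["3"]]
    pick <- sample.int(nrow(sev), 3L * length(mhr_idx), replace = TRUE)
    dx_parts$planted_mhr <- tibble::tibble(
      member_id = rep(ids[mhr_idx], each = 3L),
      service_date = sample_dates(3L * length(mhr_idx), ws, we),
      icd_version = as.integer(sev$icd_version[pick]),
      code = sev$code_prefix[pick]
    )
  }

  # planted prior PI: one baseline PI-family claim
  pp_idx <- which(role == "prior_pi")
  if (length(pp_idx) > 0) {
    dist <- pi_label_distribution()
    pick <- sample.int(nrow(dist), length(pp_idx), replace = TRUE, prob = dist$n)
    dx_parts$prior_pi <- tibble::tibble(
      member_id = ids[pp_idx],
      service_date = sample_dates(length(pp_idx), ws, we),
      icd_version = 10L,
      code = dist$code[pick]
    )
  }

  dx <- dplyr::bind_rows(c(list(empty_dx()), dx_parts))
  dx <- dplyr::arrange(dx, .data$member_id, .data$service_date, .data$code)

  # pharmacy: long antibiotic courses
  abx <- stats::runif(n) < config$long_antibiotic$prob
  rx <- tibble::tibble(
    member_id = ids[abx],
    fill_date = sample_dates(sum(abx), ws, we),
    days_supply = as.integer(sample_from(config$long_antibiotic$days, sum(abx),
                                         config$long_antibiotic$weights)),
    is_antibiotic = TRUE
  )
  rx <- dplyr::arrange(rx, .data$member_id, .data$fill_date)

  # pre-draw follow-up conversion outcomes for planted-MHR members
  pi_label <- rep(NA_character_, n)
  conc_group <- rep(NA_character_, n)
  if (length(mhr_idx) > 0) {
    v <- stats::runif(length(mhr_idx))
    to_pi <- v < config$followup_pi_conversion
    to_conc <- !to_pi & v < config$followup_pi_conversion +
      config$followup_concerning_conversion
    if (any(to_pi)) {
      dist <- pi_label_distribution()
      pi_label[mhr_idx[to_pi]] <-
        sample_from(dist$label, sum(to_pi), dist$n)
    }
    if (any(to_conc)) {
      dist <- concerning_group_distribution()
      conc_group[mhr_idx[to_conc]] <-
        sample_from(dist$group, sum(to_conc), dist$n)
    }
  }

  truth <- tibble::tibble(
    member_id = ids,
    planted_mhr = role == "mhr",
    planted_prior_pi = role == "prior_pi",
    retained = retained,
    planted_followup_pi_label = pi_label,
    planted_concerning_group = conc_group
  )

  out <- list(members = members, dx = dx, rx = rx, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_members(members, file.path(out_dir, "members.csv"))
    write_dx_claims(dx, file.path(out_dir, "dx_claims.csv"))
    write_rx_claims(rx, file.path(out_dir, "rx_claims.csv"))
    readr::write_csv(truth, file.path(out_dir, "truth.csv"))
  }
  out
}

#' Read a ground-truth file written by [generate_cohort()]
#'
#' Explicit column types: the planted label columns are mostly `NA`, so type
#' guessing would misread them.
#'
#' @param path `truth.csv` path.
#' @return tibble with the planted labels.
#' @export
read_truth <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    member_id = "c", planted_mhr = "l", planted_prior_pi = "l",
    retained = "l", planted_followup_pi_label = "c",
    planted_concerning_group = "c"
  ))
  assert_columns(out, c("member_id", "planted_mhr", "planted_prior_pi",
                        "retained", "planted_followup_pi_label",
                        "planted_concerning_group"), basename(path))
  out
}

#' Generate follow-up diagnosis claims
#'
#' Materializes the pre-drawn conversion outcomes of [generate_cohort()]:
#' every retained planted-MHR member with a planted PI label receives one
#' follow-up claim of that label's representative code, members with a
#' planted concerning group receive one claim of that group, and background
#' claims continue for all retained members at the baseline rates scaled to
#' the follow-up window length. Reproducible from the config seed.
#'
#' @param config the [sim_config()] used for the baseline.
#' @param truth the truth tibble from [generate_cohort()].
#' @param table the same [weight_table()] used for the baseline.
#' @param out_dir optional directory; writes `followup_dx.csv` when given.
#' @return tibble of follow-up diagnosis claims.
#' @export
generate_followup <- function(config, truth, table = default_weight_table(),
                              out_dir = NULL) {
  stopifnot(inherits(config, "pirisk_sim_config"))
  needed <- c("member_id", "planted_mhr", "planted_prior_pi", "retained",
              "planted_followup_pi_label", "planted_concerning_group")
  assert_columns(truth, needed, "truth")
  if (nrow(truth) != config$n_members) {
    abort_validation("generate_followup: truth does not match config n_members")
  }
  set.seed(config$seed + 1L)
  fs <- config$followup_start
  fe <- config$followup_end
  scale <- as.numeric(fe - fs) / as.numeric(config$baseline_end - config$baseline_start)

  ret <- truth[truth$retained, ]
  parts <- list()

  pools <- background_pools(table)
  rates <- config$background_rates
  for (tier in c("1", "2", "3")) {
    rate <- rates[[c("1" = "mild", "2" = "intermediate", "3" = "severe")[tier]]] * scale
    counts <- draw_counts(nrow(ret), rate, config$dispersion)
    total <- sum(counts)
    if (total == 0) next
    pool <- pools[[tier]]
    pick <- sample.int(nrow(pool), total, replace = TRUE)
    parts[[paste0("bg", tier)]] <- tibble::tibble(
      member_id = rep(ret$member_id, counts),
      service_date = sample_dates(total, fs, fe),
      icd_version = as.integer(pool$icd_version[pick]),
      code = pool$code_prefix[pick]
    )
  }

  conv_pi <- ret[!is.na(ret$planted_followup_pi_label), ]
  if (nrow(conv_pi) > 0) {
    dist <- pi_label_distribution()
    parts$pi <- tibble::tibble(
      member_id = conv_pi$member_id,
      service_date = sample_dates(nrow(conv_pi), fs, fe),
      icd_version = 10L,
      code = dist$code[match(conv_pi$planted_followup_pi_label, dist$label)]
    )
    if (any(is.na(parts$pi$code))) {
      abort_validation("generate_followup: truth carries an unknown PI label")
    }
  }

  conv_cc <- ret[!is.na(ret$planted_concerning_group), ]
  if (nrow(conv_cc) > 0) {
    reps <- lapply(conv_cc$planted_concerning_group, concerning_code_for, table)
    parts$concerning <- tibble::tibble(
      member_id = conv_cc$member_id,
      service_date = sample_dates(nrow(conv_cc), fs, fe),
      icd_version = as.integer(vapply(reps, `[[`, "", "version")),
      code = vapply(reps, `[[`, "", "code")
    )
  }

  fup <- dplyr::bind_rows(c(list(empty_dx()), parts))
  fup <- dplyr::arrange(fup, .data$member_id, .data$service_date, .data$code)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dx_claims(fup, file.path(out_dir, "followup_dx.csv"))
  }
  fup
}
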