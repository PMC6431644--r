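#' Published reference tallies
#'
#' The headline counts reported by the pediatric health-plan screening study
#' the Risk Vital Sign was deployed on: cohort sizes at every waterfall
#' stage, the Table of demographic strata, the follow-up PI-code and
#' concerning-diagnosis tallies, utilization counts, and the per-patient
#' savings figure. These are inputs for reproducing the study's printed
#' arithmetic (see [proportion()] and [estimate_savings()]) and anchors for
#' the synthetic generator's defaults; they are counts, not computed output.
#'
#' @return a named list of counts and named count vectors.
#' @export
reference_counts <- function() {
  list(
    n_main = 185892L,
    n_mhr = 2188L,
    n_focused_mhr = 1068L,
    n_chart_review = 769L,
    n_new_pi_patients = 41L,
    n_pi_codes = 46L,
    n_concerning_patients = 57L,
    n_concerning_codes = 59L,
    savings_per_patient_usd = 78166,
    main_ethnicity = c(hispanic = 111413L, none_noted = 16227L,
                       caucasian = 25091L, african_american = 27671L,
                       asian_pacific = 4948L, alaskan_american_indian = 542L),
    mhr_ethnicity = c(hispanic = 636L, none_noted = 146L, caucasian = 143L,
                      african_american = 111L, asian_pacific = 32L,
                      alaskan_american_indian = 0L),
    main_sex = c(female = 95157L, male = 90718L),
    mhr_sex = c(female = 449L, male = 619L),
    main_age = c("0-5" = 35192L, "6-12" = 89948L, "13-18" = 42220L,
                 "19-21" = 13749L, "22-64" = 4783L),
    mhr_age = c("0-5" = 439L, "6-12" = 526L, "13-18" = 77L, "19-21" = 25L,
                "22-64" = 1L),
    pi_code_tally = c("Immunodeficiency NOS" = 37L,
                      "Selective IgA deficiency" = 3L,
                      "Selective IgM deficiency" = 3L,
                      "IgG subclass deficiency" = 1L,
                      "Common variable immunodeficiency" = 1L,
                      "Primary immunodeficiency associated with other disorder" = 1L),
    concerning_tally = c(cellulitis = 18L, abscess = 14L,
                         recurrent_otitis_media = 11L,
                         recurrent_sinusitis = 5L, bacterial_pneumonia = 5L,
                         osteomyelitis = 2L, mastoiditis = 1L,
                         pulmonary_tuberculosis = 1L, lymphadenitis = 1L,
                         atypical_mycobacterial = 1L),
    utilization = c(care = 950L, pcp_visit = 555L, lab = 220L, referral = 35L)
  )
}

md_table <- function(df) {
  df[] <- lapply(df, as.character)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}

count_pct <- function(n, pct) sprintf("%d (%s)", n, format(pct, trim = TRUE))

#' Render pipeline reports as text, markdown or JSON
#'
#' Formats a [run_pipeline()] result's cohort and follow-up reports with the
#' study's stratifications and rounding: the waterfall, the demographics
#' table, the PI-code tally (`"37 (80)"` style), the concerning-diagnosis
#' tally, utilization, and the savings estimate. The JSON rendering is
#' schema-stable and inverts with [parse_report_json()].
#'
#' @param cohort_report,followup_report report lists from [run_pipeline()]
#'   (`followup_report` may be `NULL`).
#' @param format one of `"text"`, `"markdown"`, `"json"`.
#' @return a single string.
#' @export
render_report <- function(cohort_report, followup_report = NULL,
                          format = c("text", "markdown", "json")) {
  if (length(format) != 1 || !format %in% c("text", "markdown", "json")) {
    format <- match.arg(format)
  }
  cr <- cohort_report
  fr <- followup_report

  if (format == "json") {
    payload <- list(cohort_report = cr, followup_report = fr)
    return(as.character(jsonlite::toJSON(
      payload, dataframe = "columns", auto_unbox = TRUE, digits = NA,
      null = "null", na = "null"
    )))
  }

  h <- function(x) if (format == "markdown") paste0("## ", x) else toupper(x)
  tab <- function(df) {
    if (format == "markdown") md_table(df)
    else paste(utils::capture.output(print(as.data.frame(df), row.names = FALSE)),
               collapse = "\n")
  }

  parts <- c(
    if (format == "markdown") "# PI risk screening report" else "PI RISK SCREENING REPORT",
    "",
    h("Cohort"),
    sprintf("Members: %d; excluded for prior PI: %d; scored: %d.",
            cr$n_total, cr$n_excluded_prior_pi, cr$n_scored),
    sprintf("Medium-high risk (MHR): %d (%s%% of cohort).",
            cr$n_mhr, format(cr$mhr_pct_of_cohort, trim = TRUE)),
    "",
    h("Demographics (scored cohort)"),
    tab(cr$demographics_main),
    ""
  )
  if (!is.null(cr$demographics_mhr) && nrow(cr$demographics_mhr) > 0) {
    parts <- c(parts, h("Demographics (focused MHR cohort)"),
               tab(cr$demographics_mhr), "")
  }
  if (!is.null(fr)) {
    pi_tab <- if (nrow(fr$pi_code_tally) > 0) {
      tibble::tibble(Diagnosis = fr$pi_code_tally$label,
                     `Number (%)` = count_pct(fr$pi_code_tally$n_codes,
                                              fr$pi_code_tally$pct))
    } else tibble::tibble(Diagnosis = "none", `Number (%)` = "0 (0)")
    cc_tab <- if (nrow(fr$concerning_tally) > 0) {
      tibble::tibble(Diagnosis = fr$concerning_tally$label,
                     `Number (%)` = count_pct(fr$concerning_tally$n_codes,
                                              fr$concerning_tally$pct))
    } else tibble::tibble(Diagnosis = "none", `Number (%)` = "0 (0)")
    parts <- c(
      parts,
      h("Follow-up"),
      sprintf("MHR members retained at follow-up: %d.", fr$n_mhr_retained),
      sprintf("Newly coded PI: %d member(s), %d code(s).",
              fr$n_new_pi, sum(fr$pi_code_tally$n_codes)),
      sprintf("Concerning diagnoses: %d member(s), %d code(s).",
              fr$n_concerning, sum(fr$concerning_tally$n_codes)),
      "",
      h("PI diagnostic codes"),
      tab(pi_tab),
      "",
      h("Concerning diagnostic codes"),
      tab(cc_tab),
      ""
    )
    if (!is.null(fr$utilization)) {
      parts <- c(parts, h("Utilization"), tab(fr$utilization), "")
    } else {
      parts <- c(parts, h("Utilization"), "No event file supplied; unavailable.", "")
    }
    parts <- c(parts, h("Projected savings"),
               sprintf("%d identified patients x $%s = $%s (%s million USD/year).",
                       fr$n_identified,
                       format(fr$estimated_savings_usd / max(fr$n_identified, 1),
                              big.mark = ",", trim = TRUE, scientific = FALSE),
                       format(fr$estimated_savings_usd, big.mark = ",",
                              scientific = FALSE),
                       format(fr$estimated_savings_musd, trim = TRUE)))
  }
  paste(parts, collapse = "\n")
}

restore_tibble <- function(x) {
  if (is.null(x)) NULL else tibble::as_tibble(as.data.frame(x))
}

#' Parse a JSON report rendering back into report lists
#'
#' Inverse of `render_report(format = "json")`.
#'
#' @param json a JSON string.
#' @return list with `cohort_report` and `followup_report`.
#' @export
parse_report_json <- function(json) {
  raw <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  cr <- raw$cohort_report
  for (f in c("risk_histogram", "demographics_main", "demographics_mhr")) {
    cr[[f]] <- restore_tibble(cr[[f]])
  }
  fr <- raw$followup_report
  if (!is.null(fr)) {
    for (f in c("pi_code_tally", "concerning_tally", "utilization")) {
      fr[[f]] <- restore_tibble(fr[[f]])
    }
  }
  list(cohort_report = cr, followup_report = fr)
}

#' Write the standard pipeline output files
#'
#' `scores.csv`, `cohort_report.json`, `followup_report.json`,
#' `demographics.csv`, `waterfall.csv` under one directory.
#'
#' @param result a [run_pipeline()] result.
#' @param out_dir destination directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  stopifnot(inherits(result, "pirisk_pipeline_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_scores(result$scores, file.path(out_dir, "scores.csv"))
  writeLines(render_report(result$cohort_report, NULL, "json"),
             file.path(out_dir, "cohort_report.json"))
  if (!is.null(result$followup_report)) {
    writeLines(as.character(jsonlite::toJSON(
      result$followup_report, dataframe = "columns", auto_unbox = TRUE,
      digits = NA, null = "null", na = "null")),
      file.path(out_dir, "followup_report.json"))
  }
  demo <- dplyr::bind_rows(
    dplyr::mutate(result$cohort_report$demographics_main, cohort = "main"),
    dplyr::mutate(result$cohort_report$demographics_mhr, cohort = "mhr")
  )
  readr::write_csv(demo, file.path(out_dir, "demographics.csv"))
  readr::write_csv(result$waterfall, file.path(out_dir, "waterfall.csv"))
  invisible(out_dir)
}

#' Build a run manifest
#'
#' Records everything needed to reproduce a run: a hash of the configuration,
#' md5 digests of the input files, the package version, the seed(s), stage
#' row counts, and a timestamp. Two runs whose manifests agree on everything
#' but the timestamp produce identical outputs, because the pipeline is
#' deterministic given inputs, config and seed.
#'
#' @param config any configuration object (hashed structurally).
#' @param input_paths character vector of input files to digest.
#' @param seed the seed(s) used, if any.
#' @param stage_counts named list/vector of row counts per stage.
#' @return a `pirisk_manifest` list.
#' @export
run_manifest <- function(config, input_paths = character(), seed = NULL,
                         stage_counts = list()) {
  digests <- if (length(input_paths) > 0) {
    d <- tools::md5sum(input_paths)
    stats::setNames(as.character(d), basename(names(d)))
  } else character()
  structure(list(
    tool = "pirisk",
    version = as.character(utils::packageVersion("pirisk")),
    config_hash = rlang::hash(config),
    input_digests = as.list(digests),
    seed = seed,
    stage_counts = stage_counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  ), class = "pirisk_manifest")
}

#' @rdname run_manifest
#' @param manifest a `pirisk_manifest`.
#' @param path destination YAML file.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}
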