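#' Normalize an ICD diagnosis code
#'
#' Uppercases and strips periods and surrounding whitespace, the canonical
#' form used for all prefix matching ("j01.90" and "J0190" are the same code).
#' Idempotent: `normalize_code(normalize_code(x))` equals `normalize_code(x)`.
#'
#' @param raw character vector of raw code strings.
#' @return character vector of normalized codes.
#' @examples
#' normalize_code("d84.9")     # "D849"
#' normalize_code(" h66.90 ")  # "H6690"
#' @export
normalize_code <- function(raw) {
  if (!is.character(raw)) raw <- as.character(raw)
  out <- toupper(gsub("\\.", "", trimws(raw)))
  if (any(is.na(out) | out == "")) {
    abort_validation("normalize_code: empty or missing code string")
  }
  out
}

# Longest-prefix lookup of normalized codes against a prefix table.
# `tbl` needs columns code_prefix and icd_version ("9", "10" or "any").
# Returns an integer row index into tbl (NA when nothing matches). Longer
# prefixes always win; at equal length an entry with the claim's own ICD
# version beats a version-"any" entry.
match_longest_prefix <- function(codes, versions, tbl) {
  res <- rep(NA_integer_, length(codes))
  if (nrow(tbl) == 0 || length(codes) == 0) return(res)
  versions <- as.character(versions)
  key <- paste(tbl$icd_version, tbl$code_prefix, sep = ":")
  for (L in sort(unique(nchar(tbl$code_prefix)))) {
    pfx <- substr(codes, 1L, L)
    hit <- match(paste("any", pfx, sep = ":"), key)
    res[!is.na(hit)] <- hit[!is.na(hit)]
    hit <- match(paste(versions, pfx, sep = ":"), key)
    res[!is.na(hit)] <- hit[!is.na(hit)]
  }
  res
}

validate_weight_entries <- function(entries) {
  entries <- tibble::as_tibble(entries)
  assert_columns(entries,
                 c("code_prefix", "icd_version", "weight", "episodic_group", "label"),
                 "weight table")
  entries$icd_version <- as.character(entries$icd_version)
  entries$code_prefix <- normalize_code(entries$code_prefix)
  entries$episodic_group <- as.character(entries$episodic_group)
  bad_ver <- which(!entries$icd_version %in% c("9", "10", "any"))
  if (length(bad_ver) > 0) {
    abort_validation(sprintf("weight table: invalid icd_version in row(s) %s",
                             paste(bad_ver, collapse = ", ")))
  }
  if (any(is.na(entries$weight)) || any(entries$weight != as.integer(entries$weight))) {
    abort_validation("weight table: weight must be an integer")
  }
  entries$weight <- as.integer(entries$weight)
  bad_w <- which(!entries$weight %in% 1:3)
  if (length(bad_w) > 0) {
    abort_validation(sprintf("weight table: weight outside {1,2,3} in row(s) %s",
                             paste(bad_w, collapse = ", ")))
  }
  bad_g <- which(!entries$episodic_group %in% c("none", "otitis_media", "sinusitis"))
  if (length(bad_g) > 0) {
    abort_validation(sprintf("weight table: unknown episodic_group in row(s) %s",
                             paste(bad_g, collapse = ", ")))
  }
  bad_ew <- which(entries$episodic_group != "none" & entries$weight != 1L)
  if (length(bad_ew) > 0) {
    abort_validation(sprintf(
      "weight table: episodic entries must carry weight 1 (row(s) %s)",
      paste(bad_ew, collapse = ", ")))
  }
  dup <- duplicated(paste(entries$icd_version, entries$code_prefix))
  if (any(dup)) {
    abort_validation(sprintf(
      "weight table: duplicate prefix+version: %s",
      paste(unique(paste0(entries$icd_version[dup], ":", entries$code_prefix[dup])),
            collapse = ", ")))
  }
  entries
}

#' Construct a validated code-weight table
#'
#' Bundles the three lookup tables the screening algorithm needs: weighted
#' infection-code prefixes (the 1/2/3-point entries with their episodic-group
#' routing), PI diagnosis prefixes (used for exclusion and follow-up
#' detection), and the named "concerning diagnosis" groups tallied at
#' follow-up. All prefixes are normalized; lookups are longest-prefix within
#' ICD version (version `"any"` matches both).
#'
#' @param entries data frame with columns `code_prefix`, `icd_version`
#'   (`"9"`, `"10"` or `"any"`), `weight` (1, 2 or 3), `episodic_group`
#'   (`"none"`, `"otitis_media"` or `"sinusitis"`) and `label`. Episodic
#'   entries must carry weight 1.
#' @param pi_codes data frame with columns `icd_version`, `code_prefix`,
#'   `label` marking coded PI diagnoses. Must not overlap the scored
#'   infection prefixes.
#' @param concerning_groups data frame with columns `group`, `icd_version`,
#'   `code_prefix` and optionally `label`, naming the follow-up referral
#'   categories.
#' @return an object of class `pirisk_weight_table`.
#' @seealso [default_weight_table()], [read_weight_table()]
#' @export
weight_table <- function(entries, pi_codes, concerning_groups) {
  entries <- validate_weight_entries(entries)

  pi_codes <- tibble::as_tibble(pi_codes)
  assert_columns(pi_codes, c("icd_version", "code_prefix"), "pi_codes")
  pi_codes$icd_version <- as.character(pi_codes$icd_version)
  pi_codes$code_prefix <- normalize_code(pi_codes$code_prefix)
  if (!"label" %in% names(pi_codes)) pi_codes$label <- pi_codes$code_prefix
  if (any(!pi_codes$icd_version %in% c("9", "10", "any"))) {
    abort_validation("pi_codes: icd_version must be 9, 10 or any")
  }
  if (anyDuplicated(paste(pi_codes$icd_version, pi_codes$code_prefix))) {
    abort_validation("pi_codes: duplicate prefix+version")
  }
  # disjointness: a scored infection prefix may not sit inside the PI family
  for (i in seq_len(nrow(pi_codes))) {
    v <- pi_codes$icd_version[i]
    p <- pi_codes$code_prefix[i]
    comp <- entries$icd_version == v | entries$icd_version == "any" | v == "any"
    clash <- comp & (startsWith(entries$code_prefix, p) | startsWith(p, entries$code_prefix))
    if (any(clash)) {
      abort_validation(sprintf(
        "pi_codes: prefix %s overlaps scored infection prefix %s",
        p, entries$code_prefix[which(clash)[1]]))
    }
  }

  concerning_groups <- tibble::as_tibble(concerning_groups)
  assert_columns(concerning_groups, c("group", "icd_version", "code_prefix"),
                 "concerning_groups")
  concerning_groups$icd_version <- as.character(concerning_groups$icd_version)
  concerning_groups$code_prefix <- normalize_code(concerning_groups$code_prefix)
  if (!"label" %in% names(concerning_groups)) {
    concerning_groups$label <- concerning_groups$group
  }

  structure(
    list(entries = entries, pi_codes = pi_codes,
         concerning_groups = concerning_groups),
    class = "pirisk_weight_table"
  )
}

#' @export
print.pirisk_weight_table <- function(x, ...) {
  cat("<pirisk_weight_table>\n")
  cat(sprintf("  %d weighted prefixes (w1=%d, w2=%d, w3=%d; %d episodic)\n",
              nrow(x$entries),
              sum(x$entries$weight == 1), sum(x$entries$weight == 2),
              sum(x$entries$weight == 3),
              sum(x$entries$episodic_group != "none")))
  cat(sprintf("  %d PI prefixes, %d concerning-group prefixes (%d groups)\n",
              nrow(x$pi_codes), nrow(x$concerning_groups),
              length(unique(x$concerning_groups$group))))
  invisible(x)
}

#' Built-in default code-weight table
#'
#' A compact, illustrative subset of the 350+ code weighting used by the
#' published screening algorithm, covering the named anchor codes: mild
#' infections (tonsillitis, acute sinusitis, otitis media) at 1 point,
#' intermediate infections at 2, severe infections (pneumocystis pneumonia,
#' pneumococcal sepsis, bacterial meningitis) at 3, a D80-D84 / ICD-9 279
#' PI prefix family, and the ten concerning-diagnosis referral groups.
#' The full weighting is distributed as supplementary material of the source
#' study and can be supplied via [read_weight_table()]; this default is an
#' approximation suitable for simulation and testing, not a clinical grouper.
#'
#' @return a [weight_table()] object.
#' @export
default_weight_table <- function() {
  entries <- tibble::tribble(
    ~code_prefix, ~icd_version, ~weight, ~episodic_group, ~label,
    # mild (1 point)
    "J03",  "10", 1L, "none",         "Acute tonsillitis",
    "J35",  "10", 1L, "none",         "Chronic tonsillitis and adenoiditis",
    "463",  "9",  1L, "none",         "Acute tonsillitis",
    "474",  "9",  1L, "none",         "Chronic tonsillitis and adenoiditis",
    "J02",  "10", 1L, "none",         "Acute pharyngitis",
    "462",  "9",  1L, "none",         "Acute pharyngitis",
    "J32",  "10", 1L, "none",         "Chronic sinusitis",
    "473",  "9",  1L, "none",         "Chronic sinusitis",
    "J01",  "10", 1L, "sinusitis",    "Acute sinusitis",
    "461",  "9",  1L, "sinusitis",    "Acute sinusitis",
    "H66",  "10", 1L, "otitis_media", "Suppurative and unspecified otitis media",
    "H65",  "10", 1L, "otitis_media", "Nonsuppurative otitis media",
    "382",  "9",  1L, "otitis_media", "Suppurative and unspecified otitis media",
    "381",  "9",  1L, "otitis_media", "Nonsuppurative otitis media",
    # intermediate (2 points)
    "J18",  "10", 2L, "none",         "Pneumonia, unspecified organism",
    "486",  "9",  2L, "none",         "Pneumonia, organism unspecified",
    "J15",  "10", 2L, "none",         "Bacterial pneumonia",
    "482",  "9",  2L, "none",         "Other bacterial pneumonia",
    "N390", "10", 2L, "none",         "Urinary tract infection",
    "5990", "9",  2L, "none",         "Urinary tract infection",
    "L03",  "10", 2L, "none",         "Cellulitis",
    "682",  "9",  2L, "none",         "Cellulitis and abscess",
    "L02",  "10", 2L, "none",         "Cutaneous abscess, furuncle and carbuncle",
    "680",  "9",  2L, "none",         "Carbuncle and furuncle",
    "H70",  "10", 2L, "none",         "Mastoiditis",
    "383",  "9",  2L, "none",         "Mastoiditis",
    "M86",  "10", 2L, "none",         "Osteomyelitis",
    "730",  "9",  2L, "none",         "Osteomyelitis",
    "L04",  "10", 2L, "none",         "Acute lymphadenitis",
    "683",  "9",  2L, "none",         "Acute lymphadenitis",
    # severe (3 points)
    "B59",  "10", 3L, "none",         "Pneumocystosis",
    "1363", "9",  3L, "none",         "Pneumocystosis",
    "A403", "10", 3L, "none",         "Sepsis due to Streptococcus pneumoniae",
    "0382", "9",  3L, "none",         "Pneumococcal septicemia",
    "G00",  "10", 3L, "none",         "Bacterial meningitis",
    "320",  "9",  3L, "none",         "Bacterial meningitis",
    "A41",  "10", 3L, "none",         "Other sepsis",
    "038",  "9",  3L, "none",         "Septicemia",
    "A15",  "10", 3L, "none",         "Respiratory tuberculosis",
    "011",  "9",  3L, "none",         "Pulmonary tuberculosis",
    "A31",  "10", 3L, "none",         "Infection due to other mycobacteria",
    "031",  "9",  3L, "none",         "Other mycobacterial diseases"
  )

  pi_codes <- tibble::tribble(
    ~icd_version, ~code_prefix, ~label,
    "10", "D849", "Immunodeficiency NOS",
    "10", "D802", "Selective IgA deficiency",
    "10", "D804", "Selective IgM deficiency",
    "10", "D803", "IgG subclass deficiency",
    "10", "D83",  "Common variable immunodeficiency",
    "10", "D82",  "Primary immunodeficiency associated with other disorder",
    "10", "D80",  "Other antibody deficiency",
    "10", "D81",  "Combined immunodeficiency",
    "10", "D84",  "Other immunodeficiency",
    "9",  "279",  "Disorders involving the immune mechanism"
  )

  concerning_groups <- tibble::tribble(
    ~group,                   ~icd_version, ~code_prefix, ~label,
    "cellulitis",              "10", "L03", "Cellulitis",
    "cellulitis",              "9",  "682", "Cellulitis",
    "abscess",                 "10", "L02", "Abscess",
    "abscess",                 "9",  "680", "Abscess",
    "recurrent_otitis_media",  "10", "H66", "Recurrent otitis media",
    "recurrent_otitis_media",  "10", "H65", "Recurrent otitis media",
    "recurrent_otitis_media",  "9",  "382", "Recurrent otitis media",
    "recurrent_sinusitis",     "10", "J32", "Recurrent sinusitis",
    "recurrent_sinusitis",     "9",  "473", "Recurrent sinusitis",
    "bacterial_pneumonia",     "10", "J15", "Bacterial pneumonia",
    "bacterial_pneumonia",     "9",  "482", "Bacterial pneumonia",
    "osteomyelitis",           "10", "M86", "Osteomyelitis",
    "osteomyelitis",           "9",  "730", "Osteomyelitis",
    "mastoiditis",             "10", "H70", "Mastoiditis",
    "mastoiditis",             "9",  "383", "Mastoiditis",
    "pulmonary_tuberculosis",  "10", "A15", "Pulmonary tuberculosis",
    "pulmonary_tuberculosis",  "9",  "011", "Pulmonary tuberculosis",
    "lymphadenitis",           "10", "L04", "Lymphadenitis",
    "lymphadenitis",           "9",  "683", "Lymphadenitis",
    "atypical_mycobacterial",  "10", "A31", "Atypical mycobacterial infection",
    "atypical_mycobacterial",  "9",  "031", "Atypical mycobacterial infection"
  )

  weight_table(entries, pi_codes, concerning_groups)
}

#' Read a code-weight table from delimited files
#'
#' @param path CSV with columns `code_prefix,icd_version,weight,episodic_group,label`.
#' @param pi_codes_path optional text file, one PI prefix per line as
#'   `version:prefix` or `version:prefix:label`. Defaults to the built-in
#'   D80-D84 / 279 family when omitted.
#' @param concerning_groups_path optional CSV with columns
#'   `group,icd_version,code_prefix` (and optionally `label`). Defaults to the
#'   built-in ten referral groups when omitted.
#' @return a [weight_table()] object.
#' @export
read_weight_table <- function(path, pi_codes_path = NULL,
                              concerning_groups_path = NULL) {
  entries <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  assert_columns(entries,
                 c("code_prefix", "icd_version", "weight", "episodic_group", "label"),
                 basename(path))
  w <- suppressWarnings(as.numeric(entries$weight))
  if (any(is.na(w))) {
    abort_validation(sprintf("%s: non-numeric weight in row(s) %s",
                             basename(path),
                             paste(which(is.na(w)), collapse = ", ")))
  }
  entries$weight <- w

  defaults <- default_weight_table()
  pi_codes <- if (is.null(pi_codes_path)) defaults$pi_codes else {
    lines <- readLines(pi_codes_path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, ":", fixed = TRUE)
    bad <- lengths(parts) < 2
    if (any(bad)) {
      abort_format(sprintf("%s: expected version:prefix[:label] on line(s) %s",
                           basename(pi_codes_path),
                           paste(which(bad), collapse = ", ")))
    }
    tibble::tibble(
      icd_version = vapply(parts, `[`, "", 1L),
      code_prefix = vapply(parts, `[`, "", 2L),
      label = vapply(parts, function(p) if (length(p) >= 3) p[3] else p[2], "")
    )
  }
  concerning <- if (is.null(concerning_groups_path)) defaults$concerning_groups else {
    readr::read_csv(concerning_groups_path, col_types = readr::cols(.default = "c"))
  }
  weight_table(entries, pi_codes, concerning)
}

#' Write a code-weight table to delimited files
#'
#' Inverse of [read_weight_table()]: writing then reading reproduces the
#' table element for element.
#'
#' @param table a [weight_table()] object.
#' @param path destination CSV for the weighted entries.
#' @param pi_codes_path optional destination for the PI prefix list.
#' @param concerning_groups_path optional destination for the referral groups.
#' @export
write_weight_table <- function(table, path, pi_codes_path = NULL,
                               concerning_groups_path = NULL) {
  stopifnot(inherits(table, "pirisk_weight_table"))
  readr::write_csv(table$entries, path)
  if (!is.null(pi_codes_path)) {
    writeLines(paste(table$pi_codes$icd_version, table$pi_codes$code_prefix,
                     table$pi_codes$label, sep = ":"),
               pi_codes_path)
  }
  if (!is.null(concerning_groups_path)) {
    readr::write_csv(table$concerning_groups, concerning_groups_path)
  }
  invisible(path)
}

#' Match diagnosis claims against the weighted prefixes
#'
#' Longest-prefix lookup of each claim's normalized code within its ICD
#' version. Claims matching no entry get weight 0 and group `"none"`.
#'
#' @param dx_claims diagnosis-claim data frame (`member_id`, `service_date`,
#'   `icd_version`, `code`).
#' @param table a [weight_table()] object.
#' @return `dx_claims` with `weight`, `episodic_group`, `matched_prefix` and
#'   `matched_label` columns appended.
#' @export
match_weights <- function(dx_claims, table) {
  stopifnot(inherits(table, "pirisk_weight_table"))
  idx <- match_longest_prefix(dx_claims$code, dx_claims$icd_version, table$entries)
  dx_claims$weight <- ifelse(is.na(idx), 0L, table$entries$weight[idx])
  dx_claims$episodic_group <-
    ifelse(is.na(idx), "none", table$entries$episodic_group[idx])
  dx_claims$matched_prefix <-
    ifelse(is.na(idx), NA_character_, table$entries$code_prefix[idx])
  dx_claims$matched_label <-
    ifelse(is.na(idx), NA_character_, table$entries$label[idx])
  dx_claims
}
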