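#' @title Claims file input and output
#' @description Readers for the three delimited inputs the pipeline consumes
#'   (member roster, diagnosis claims, pharmacy claims) and matching writers.
#'   All files are comma-separated UTF-8 with a header row; dates are
#'   ISO-8601 (`YYYY-MM-DD`); enrollment and supply intervals are half-open
#'   `[start, end)`. Rows violating an invariant are never silently dropped:
#'   each reader returns the accepted records with a `rejects` attribute
#'   listing every refused row and the reason, so that
#'   `rows in = rows accepted + rows rejected` always holds.
#' @name claims_io
NULL

ETHNICITY_LEVELS <- c("hispanic", "none_noted", "caucasian", "african_american",
                      "asian_pacific", "alaskan_american_indian")
SEX_LEVELS <- c("female", "male", "unknown")

# earliest plausible service date; claims predating it are data errors
MIN_PLAUSIBLE_DATE <- as.Date("1970-01-01")

attach_rejects <- function(records, rejects) {
  attr(records, "rejects") <- tibble::as_tibble(rejects)
  records
}

#' Rejected rows of a reader result
#'
#' @param x a data frame returned by [read_members()], [read_dx_claims()] or
#'   [read_rx_claims()].
#' @return tibble with columns `row`, `member_id`, `reason`.
#' @export
rejects <- function(x) {
  attr(x, "rejects") %||%
    tibble::tibble(row = integer(), member_id = character(), reason = character())
}

#' Read a member roster
#'
#' One member per row with demographic and enrollment fields. Rows with
#' unparseable dates, an enrollment interval ending before it starts
#' (reason `"interval"`), or an unknown sex/ethnicity level are rejected.
#' A duplicated `member_id` among otherwise-valid rows is an error (the
#' roster is the identity backbone of the analysis, so duplicates cannot be
#' attributed to a single bad row).
#'
#' @param path CSV with header
#'   `member_id,birth_date,sex,ethnicity,enrolled_from,enrolled_to`.
#' @return tibble of members with a `rejects` attribute (see [rejects()]).
#' @export
read_members <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  assert_columns(raw, c("member_id", "birth_date", "sex", "ethnicity",
                        "enrolled_from", "enrolled_to"), basename(path))
  birth <- parse_date_safe(raw$birth_date)
  from <- parse_date_safe(raw$enrolled_from)
  to <- parse_date_safe(raw$enrolled_to)
  sex <- tolower(trimws(raw$sex %||% ""))
  eth <- tolower(trimws(raw$ethnicity %||% ""))

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(birth) | is.na(from) | is.na(to)] <- "date"
  reason[is.na(reason) & !sex %in% SEX_LEVELS] <- "sex"
  reason[is.na(reason) & !eth %in% ETHNICITY_LEVELS] <- "ethnicity"
  reason[is.na(reason) & to < from] <- "interval"
  reason[is.na(reason) & (is.na(raw$member_id) | raw$member_id == "")] <- "member_id"

  ok <- is.na(reason)
  members <- tibble::tibble(
    member_id = raw$member_id[ok],
    birth_date = birth[ok],
    sex = sex[ok],
    ethnicity = eth[ok],
    enrolled_from = from[ok],
    enrolled_to = to[ok]
  )
  if (anyDuplicated(members$member_id)) {
    dups <- unique(members$member_id[duplicated(members$member_id)])
    abort_validation(sprintf("%s: duplicate member_id: %s", basename(path),
                             paste(dups, collapse = ", ")))
  }
  attach_rejects(members, tibble::tibble(
    row = which(!ok),
    member_id = raw$member_id[!ok],
    reason = reason[!ok]
  ))
}

#' Read diagnosis claims
#'
#' ICD codes are normalized with [normalize_code()] before storage. Rows with
#' an unparseable service date, a date outside the plausible range (pre-1970
#' or in the future), an ICD version other than 9/10, or an empty code are
#' rejected with a reason.
#'
#' @param path CSV with header `member_id,service_date,icd_version,code`.
#' @return tibble of diagnosis claims with a `rejects` attribute.
#' @export
read_dx_claims <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  assert_columns(raw, c("member_id", "service_date", "icd_version", "code"),
                 basename(path))
  parse_dx_rows(raw)
}

parse_dx_rows <- function(raw) {
  date <- parse_date_safe(raw$service_date)
  ver <- suppressWarnings(as.integer(raw$icd_version))
  code <- toupper(gsub("\\.", "", trimws(raw$code %||% "")))

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(date)] <- "date"
  reason[is.na(reason) & (date < MIN_PLAUSIBLE_DATE | date > Sys.Date())] <- "date_range"
  reason[is.na(reason) & (is.na(ver) | !ver %in% c(9L, 10L))] <- "icd_version"
  reason[is.na(reason) & (is.na(code) | code == "")] <- "code"
  reason[is.na(reason) & (is.na(raw$member_id) | raw$member_id == "")] <- "member_id"

  ok <- is.na(reason)
  attach_rejects(
    tibble::tibble(member_id = raw$member_id[ok], service_date = date[ok],
                   icd_version = ver[ok], code = code[ok]),
    tibble::tibble(row = which(!ok), member_id = raw$member_id[!ok],
                   reason = reason[!ok])
  )
}

#' Read pharmacy claims
#'
#' Rows with an unparseable fill date, a non-positive `days_supply`, or an
#' uninterpretable antibiotic flag are rejected. Only `is_antibiotic = TRUE`
#' fills ever contribute to scoring; non-antibiotic fills are retained so the
#' file round-trips.
#'
#' @param path CSV with header `member_id,fill_date,days_supply,is_antibiotic`.
#' @return tibble of pharmacy claims with a `rejects` attribute.
#' @export
read_rx_claims <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  assert_columns(raw, c("member_id", "fill_date", "days_supply", "is_antibiotic"),
                 basename(path))
  parse_rx_rows(raw)
}

parse_rx_rows <- function(raw) {
  date <- parse_date_safe(raw$fill_date)
  supply <- suppressWarnings(as.integer(raw$days_supply))
  abx_raw <- tolower(trimws(raw$is_antibiotic %||% ""))
  abx <- ifelse(abx_raw %in% c("true", "t", "1", "yes"), TRUE,
                ifelse(abx_raw %in% c("false", "f", "0", "no"), FALSE, NA))

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(date)] <- "date"
  reason[is.na(reason) & (is.na(supply) | supply < 1L)] <- "days_supply"
  reason[is.na(reason) & is.na(abx)] <- "is_antibiotic"
  reason[is.na(reason) & (is.na(raw$member_id) | raw$member_id == "")] <- "member_id"

  ok <- is.na(reason)
  attach_rejects(
    tibble::tibble(member_id = raw$member_id[ok], fill_date = date[ok],
                   days_supply = supply[ok], is_antibiotic = abx[ok]),
    tibble::tibble(row = which(!ok), member_id = raw$member_id[!ok],
                   reason = reason[!ok])
  )
}

#' Read diagnosis and pharmacy claims together
#'
#' Accepts either two separate files, or a single combined file carrying a
#' `record_type` column (`"dx"` / `"rx"`) beside the union of the two schemas.
#'
#' @param dx_path,rx_path paths to the separate claim files, or `dx_path`
#'   alone pointing at a combined file with a `record_type` column.
#' @return list with elements `dx` and `rx`, each carrying its own `rejects`
#'   attribute.
#' @export
read_claims <- function(dx_path, rx_path = NULL) {
  if (!is.null(rx_path)) {
    return(list(dx = read_dx_claims(dx_path), rx = read_rx_claims(rx_path)))
  }
  raw <- readr::read_csv(dx_path, col_types = readr::cols(.default = "c"))
  if (!"record_type" %in% names(raw)) {
    abort_format(sprintf(
      "%s: combined claim files need a record_type column ('dx'/'rx')",
      basename(dx_path)))
  }
  list(
    dx = parse_dx_rows(assert_columns(raw[raw$record_type == "dx", ],
                                      c("member_id", "service_date",
                                        "icd_version", "code"),
                                      basename(dx_path))),
    rx = parse_rx_rows(assert_columns(raw[raw$record_type == "rx", ],
                                      c("member_id", "fill_date",
                                        "days_supply", "is_antibiotic"),
                                      basename(dx_path)))
  )
}

#' @rdname claims_io
#' @param members,dx_claims,rx_claims data frames as returned by the readers.
#' @param path destination file.
#' @export
write_members <- function(members, path) {
  readr::write_csv(members[, c("member_id", "birth_date", "sex", "ethnicity",
                               "enrolled_from", "enrolled_to")], path)
  invisible(path)
}

#' @rdname claims_io
#' @export
write_dx_claims <- function(dx_claims, path) {
  readr::write_csv(dx_claims[, c("member_id", "service_date", "icd_version",
                                 "code")], path)
  invisible(path)
}

#' @rdname claims_io
#' @export
write_rx_claims <- function(rx_claims, path) {
  out <- rx_claims[, c("member_id", "fill_date", "days_supply", "is_antibiotic")]
  out$is_antibiotic <- ifelse(out$is_antibiotic, "true", "false")
  readr::write_csv(out, path)
  invisible(path)
}
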