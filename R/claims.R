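#' Claims schema configuration
#'
#' Maps the column names of a delimited claims file onto the fields the
#' pipeline needs. Any visit-level file with a header can be ingested by
#' renaming through this mapping.
#'
#' @param patient_id,visit_date,provider_id,primary_dx,expense,insurance_type
#'   column names in the input file.
#' @param date_format format string passed to [as.Date()].
#' @param delim field delimiter; `NULL` autodetects from the file extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @param tolerate_bad_rows if `TRUE`, rows with unparseable dates or amounts
#'   are dropped (and counted); if `FALSE` they raise an error.
#' @return a `claims_schema` list.
#' @export
claims_schema <- function(patient_id = "patient_id",
                          visit_date = "visit_date",
                          provider_id = "provider_id",
                          primary_dx = "primary_dx",
                          expense = "expense",
                          insurance_type = "insurance_type",
                          date_format = "%Y-%m-%d",
                          delim = NULL,
                          tolerate_bad_rows = FALSE) {
  structure(list(patient_id = patient_id, visit_date = visit_date,
                 provider_id = provider_id, primary_dx = primary_dx,
                 expense = expense, insurance_type = insurance_type,
                 date_format = date_format, delim = delim,
                 tolerate_bad_rows = tolerate_bad_rows),
            class = "claims_schema")
}

#' Normalize ICD-10 codes
#'
#' Uppercases and strips dots, so `"i10.x02"` becomes `"I10X02"`. Idempotent.
#'
#' @param codes character vector of raw ICD-10 codes.
#' @return normalized character vector.
#' @export
normalize_icd10 <- function(codes) {
  gsub(".", "", toupper(trimws(codes)), fixed = TRUE)
}

#' Read a visit-level claims file
#'
#' Reads a delimited text file of reimbursement lines and returns one row per
#' visit, where a visit is a unique (patient, date, provider) triple: claim
#' lines sharing that triple are collapsed into one visit whose expense is the
#' line sum (the first diagnosis code of the group is kept). ICD-10 codes are
#' normalized with [normalize_icd10()].
#'
#' @param path path to a CSV/TSV file with a header.
#' @param schema a [claims_schema()].
#' @return a tibble of visits with columns `patient_id`, `visit_date`,
#'   `provider_id`, `primary_dx`, `expense`, `insurance_type`, and attributes
#'   `n_lines_in` (raw line count) and `n_bad_rows` (rows dropped for parse
#'   failures when tolerated).
#' @export
read_claims <- function(path, schema = claims_schema()) {
  if (!file.exists(path)) stop("claims file not found: ", path)
  delim <- schema$delim %||%
    (if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ",")
  raw <- utils::read.delim(path, sep = delim, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  needed <- c("patient_id", "visit_date", "provider_id", "primary_dx",
              "expense", "insurance_type")
  for (field in needed) {
    col <- schema[[field]]
    if (!col %in% names(raw)) {
      stop("claims file is missing required column '", col,
           "' (mapped to field '", field, "')")
    }
  }
  df <- tibble::tibble(
    patient_id = as.character(raw[[schema$patient_id]]),
    visit_date = as.Date(raw[[schema$visit_date]], format = schema$date_format),
    provider_id = as.character(raw[[schema$provider_id]]),
    primary_dx = normalize_icd10(raw[[schema$primary_dx]]),
    expense = suppressWarnings(as.numeric(raw[[schema$expense]])),
    insurance_type = as.character(raw[[schema$insurance_type]])
  )
  bad <- is.na(df$visit_date) | is.na(df$expense)
  if (any(bad)) {
    lines <- which(bad) + 1L  # header is line 1
    if (!schema$tolerate_bad_rows) {
      stop("unparseable date or amount on line(s): ",
           paste(utils::head(lines, 10L), collapse = ", "),
           if (length(lines) > 10L) " ..." else "")
    }
    warning(length(lines), " row(s) dropped for unparseable date or amount")
    df <- df[!bad, , drop = FALSE]
  }
  if (any(df$expense < 0)) stop("negative expense amounts in claims file")
  if (any(!nzchar(df$primary_dx))) stop("empty diagnosis code after normalization")

  out <- df |>
    dplyr::group_by(.data$patient_id, .data$visit_date, .data$provider_id) |>
    dplyr::summarise(primary_dx = .data$primary_dx[1L],
                     expense = sum(.data$expense),
                     insurance_type = .data$insurance_type[1L],
                     .groups = "drop")
  attr(out, "n_lines_in") <- nrow(raw)
  attr(out, "n_bad_rows") <- sum(bad)
  out
}

# ICD-10 prefixes identifying hypertension in the primary diagnosis
HYPERTENSION_PREFIXES <- c("I10", "I11", "I12", "I13", "I15")

#' Is a patient a hypertension case?
#'
#' `TRUE` iff any normalized primary diagnosis starts with one of the
#' hypertension ICD-10 prefixes I10-I13, I15.
#'
#' @param dx_codes character vector of primary diagnosis codes (one patient).
#' @return logical scalar; `FALSE` for an empty vector.
#' @export
is_hypertension_case <- function(dx_codes) {
  if (length(dx_codes) == 0L) return(FALSE)
  codes <- normalize_icd10(dx_codes)
  any(substr(codes, 1L, 3L) %in% HYPERTENSION_PREFIXES)
}

#' Build patient-year panels from visit records
#'
#' Aggregates visits to the patient-year level over a fixed observation
#' horizon. Year index `t = calendar year - baseline_year` runs 0..T-1; every
#' patient gets a row for every year, with `n_visits = 0` where no visits
#' occurred. Visits dated outside the window are excluded and counted.
#'
#' @param visits a visit tibble as returned by [read_claims()].
#' @param demographics optional tibble with columns `patient_id`, `sex`
#'   (`"male"`/`"female"`), `birth_date` (Date or year), `insurance_type`
#'   (`"employee"`/`"resident"`).
#' @param baseline_year first calendar year of the window.
#' @param horizon number of annual windows T (default 6).
#' @return a `coc_panels` object: a list with
#'   \describe{
#'     \item{patients}{one row per patient: covariates, pooled diagnosis codes
#'       (list-column), baseline age.}
#'     \item{years}{one row per patient-year: `t`, `year`, `n_visits`,
#'       `expense_total`, and `providers`, a list-column of per-provider visit
#'       tallies.}
#'   }
#'   plus `baseline_year` and `horizon`; attribute `n_visits_outside_window`
#'   counts excluded visits.
#' @export
build_panels <- function(visits, demographics = NULL,
                         baseline_year, horizon = 6L) {
  if (nrow(visits) == 0L) {
    return(new_coc_panels(empty_patients(), empty_years(),
                          baseline_year, horizon, 0L))
  }
  yr <- as.integer(format(visits$visit_date, "%Y"))
  inside <- yr >= baseline_year & yr <= baseline_year + horizon - 1L
  n_out <- sum(!inside)
  visits <- visits[inside, , drop = FALSE]
  yr <- yr[inside]
  if (nrow(visits) == 0L) {
    return(new_coc_panels(empty_patients(), empty_years(),
                          baseline_year, horizon, n_out))
  }
  visits$t <- yr - as.integer(baseline_year)

  years <- visits |>
    dplyr::group_by(.data$patient_id, .data$t) |>
    dplyr::summarise(
      n_visits = dplyr::n(),
      expense_total = sum(.data$expense),
      providers = list(table2tally(.data$provider_id)),
      .groups = "drop")
  # complete to the full horizon with empty years
  grid <- tidyr::expand_grid(patient_id = unique(visits$patient_id),
                             t = 0:(horizon - 1L))
  years <- dplyr::left_join(grid, years, by = c("patient_id", "t"))
  years$n_visits[is.na(years$n_visits)] <- 0L
  years$expense_total[is.na(years$expense_total)] <- 0
  years$providers[vapply(years$providers, is.null, logical(1))] <-
    list(integer(0))
  years$year <- as.integer(baseline_year) + years$t
  years <- years[order(years$patient_id, years$t),
                 c("patient_id", "t", "year", "n_visits", "expense_total",
                   "providers")]

  patients <- visits |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(dx_codes = list(unique(.data$primary_dx)),
                     insurance_type = .data$insurance_type[1L],
                     .groups = "drop")
  if (!is.null(demographics)) {
    demo <- demographics
    demo$patient_id <- as.character(demo$patient_id)
    patients <- dplyr::left_join(
      patients, demo[setdiff(names(demo), "insurance_type")],
      by = "patient_id")
    if ("insurance_type" %in% names(demo)) {
      # demographics file wins when both carry the insurance type
      ins <- demo$insurance_type[match(patients$patient_id, demo$patient_id)]
      patients$insurance_type <- ifelse(is.na(ins), patients$insurance_type, ins)
    }
    if ("birth_date" %in% names(patients)) {
      patients$age_baseline <- age_at(patients$birth_date, baseline_year)
    }
  }
  new_coc_panels(patients, years, baseline_year, horizon, n_out)
}

new_coc_panels <- function(patients, years, baseline_year, horizon, n_out) {
  structure(list(patients = patients, years = years,
                 baseline_year = as.integer(baseline_year),
                 horizon = as.integer(horizon)),
            n_visits_outside_window = n_out,
            class = "coc_panels")
}

empty_patients <- function() {
  tibble::tibble(patient_id = character(), dx_codes = list(),
                 insurance_type = character())
}
empty_years <- function() {
  tibble::tibble(patient_id = character(), t = integer(), year = integer(),
                 n_visits = integer(), expense_total = numeric(),
                 providers = list())
}

table2tally <- function(ids) {
  tab <- table(ids)
  stats::setNames(as.integer(tab), names(tab))
}

# Age in completed years at Jan 1 of baseline_year. A bare birth year gives
# baseline_year - birth_year.
age_at <- function(birth, baseline_year) {
  if (inherits(birth, "Date")) {
    ref <- as.Date(sprintf("%d-01-01", baseline_year))
    yrs <- as.integer(format(ref, "%Y")) - as.integer(format(birth, "%Y"))
    had_birthday <- format(birth, "%m-%d") <= format(ref, "%m-%d")
    as.integer(yrs - !had_birthday)
  } else {
    as.integer(baseline_year) - as.integer(birth)
  }
}

#' @export
print.coc_panels <- function(x, ...) {
  cat("<coc_panels> ", nrow(x$patients), " patients, horizon ", x$horizon,
      " years from ", x$baseline_year, "\n", sep = "")
  invisible(x)
}

#' Number of patients in a panel set
#' @param panels a `coc_panels` object.
#' @return integer count.
#' @export
n_patients <- function(panels) nrow(panels$patients)

#' Apply the cohort inclusion filters
#'
#' Keeps a patient iff (a) aged at least `adult_age` on Jan 1 of the baseline
#' year, (b) at least `min_qualifying_years` years in the window have
#' `n_visits >= min_visits_per_year`, and (c) the patient has a hypertension
#' primary diagnosis ([is_hypertension_case()]). Idempotent.
#'
#' @param panels a `coc_panels` object.
#' @param min_visits_per_year per-year visit minimum (default 3).
#' @param min_qualifying_years minimum number of qualifying years (default 3).
#' @param adult_age minimum age at baseline (default 18).
#' @return filtered `coc_panels`; attribute `disposition` is a tibble
#'   (`patient_id`, `reason`) with one row per excluded patient, reason being
#'   the first failed check among `underage`, `too_few_qualifying_years`,
#'   `not_hypertension`.
#' @export
cohort_filter <- function(panels, min_visits_per_year = 3L,
                          min_qualifying_years = 3L, adult_age = 18L) {
  pts <- panels$patients
  qual <- panels$years |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_qual = sum(.data$n_visits >= min_visits_per_year),
                     .groups = "drop")
  n_qual <- qual$n_qual[match(pts$patient_id, qual$patient_id)]
  n_qual[is.na(n_qual)] <- 0L
  age <- if ("age_baseline" %in% names(pts)) pts$age_baseline else
    rep(NA_integer_, nrow(pts))
  htn <- vapply(pts$dx_codes, is_hypertension_case, logical(1))

  reason <- rep(NA_character_, nrow(pts))
  reason[!is.na(age) & age < adult_age] <- "underage"
  reason[is.na(reason) & n_qual < min_qualifying_years] <-
    "too_few_qualifying_years"
  reason[is.na(reason) & !htn] <- "not_hypertension"
  keep <- is.na(reason)

  kept_ids <- pts$patient_id[keep]
  out <- new_coc_panels(
    pts[keep, , drop = FALSE],
    panels$years[panels$years$patient_id %in% kept_ids, , drop = FALSE],
    panels$baseline_year, panels$horizon,
    attr(panels, "n_visits_outside_window") %||% 0L)
  attr(out, "disposition") <- tibble::tibble(
    patient_id = pts$patient_id[!keep], reason = reason[!keep])
  out
}

#' Patient-year panel as a tidy data frame
#'
#' One row per patient-year with visit count, number of distinct providers,
#' COCI (NA below the visit minimum) and expense total; suitable for writing
#' to CSV.
#'
#' @param panels a `coc_panels` object.
#' @param min_visits_per_year visit minimum below which COCI is missing.
#' @return a tibble.
#' @export
panel_table <- function(panels, min_visits_per_year = 3L) {
  y <- panels$years
  tibble::tibble(
    patient_id = y$patient_id, t = y$t, year = y$year,
    n_visits = y$n_visits,
    n_providers = vapply(y$providers, length, integer(1)),
    coci = vapply(y$providers, coci, numeric(1),
                  min_visits = min_visits_per_year),
    expense_total = y$expense_total)
}

#' COCI matrix for trajectory fitting
#'
#' @param panels a `coc_panels` object.
#' @param min_visits_per_year visit minimum below which the year is missing.
#' @return numeric matrix, patients x years, `NA` for missing years; rownames
#'   are patient ids.
#' @export
coci_matrix <- function(panels, min_visits_per_year = 3L) {
  tab <- panel_table(panels, min_visits_per_year)
  ids <- panels$patients$patient_id
  m <- matrix(NA_real_, nrow = length(ids), ncol = panels$horizon,
              dimnames = list(ids, paste0("t", 0:(panels$horizon - 1L))))
  m[cbind(match(tab$patient_id, ids), tab$t + 1L)] <- tab$coci
  m
}
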