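#' Bice-Boxerman Continuity of Care Index
#'
#' For a patient-year with N visits spread over providers with visit counts
#' n_i, COCI = sum_i n_i (n_i - 1) / (N (N - 1)): the probability that two
#' distinct visits drawn from the year are to the same provider. 1 means all
#' visits went to a single provider; 0 means every visit went to a different
#' provider. Years with fewer than `min_visits` visits do not support a
#' meaningful concentration estimate and return `NA`.
#'
#' @param provider_counts integer vector of visits per distinct provider
#'   (names optional; only the tally matters).
#' @param min_visits minimum number of visits for a defined index (default 3).
#' @return numeric scalar in \[0, 1\], or `NA` when N < `min_visits`.
#' @export
#' @examples
#' coci(c(A = 3, B = 1))  # 0.5
coci <- function(provider_counts, min_visits = 3L) {
  n_i <- as.numeric(provider_counts)
  if (any(n_i < 0)) stop("provider counts must be non-negative")
  n_i <- n_i[n_i > 0]
  N <- sum(n_i)
  if (N < min_visits) return(NA_real_)
  sum(n_i * (n_i - 1)) / (N * (N - 1))
}

#' Load an updated-Charlson weight table
#'
#' The condition categories, their ICD-10 prefixes, integer weights and
#' severity hierarchy are data, not code: the packaged default
#' (`inst/extdata/upcci_weights.csv`) carries the 2011 recalibrated weights
#' with standard ICD-10 coding-algorithm prefixes, and can be replaced by any
#' file with the same columns.
#'
#' @param path CSV with columns `category`, `icd10_prefixes`
#'   (semicolon-separated), `weight`, `supersedes` (optional category name:
#'   when both categories are present, the superseded one is not counted).
#'   `NULL` loads the packaged default.
#' @return a tibble with `prefixes` as a list-column.
#' @export
load_upcci_weights <- function(path = NULL) {
  path <- path %||% system.file("extdata", "upcci_weights.csv",
                                package = "coctraj", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("category", "icd10_prefixes", "weight")) {
    if (!col %in% names(df)) stop("weight table is missing column '", col, "'")
  }
  if (!"supersedes" %in% names(df)) df$supersedes <- ""
  if (any(df$weight < 0) || any(df$weight != round(df$weight))) {
    stop("weights must be non-negative integers")
  }
  bad <- nzchar(df$supersedes) & !(df$supersedes %in% df$category)
  if (any(bad)) {
    stop("supersedes refers to unknown category: ",
         paste(df$supersedes[bad], collapse = ", "))
  }
  tibble::tibble(
    category = df$category,
    prefixes = strsplit(normalize_icd10(df$icd10_prefixes), ";", fixed = TRUE),
    weight = as.integer(df$weight),
    supersedes = df$supersedes)
}

#' Updated Charlson Comorbidity Index from ICD-10 codes
#'
#' Maps diagnosis codes to comorbidity categories by ICD-10 prefix, applies
#' the severity hierarchies (metastatic solid tumour supersedes any
#' malignancy; moderate/severe liver disease supersedes mild; diabetes with
#' chronic complication supersedes uncomplicated diabetes), and sums the
#' 2011-update weights, each category counted at most once.
#'
#' @param dx_codes character vector of ICD-10 codes observed for a patient
#'   (normalized internally).
#' @param weights a weight table from [load_upcci_weights()].
#' @return integer score (0 for no matching codes).
#' @export
upcci <- function(dx_codes, weights = load_upcci_weights()) {
  if (length(dx_codes) == 0L) return(0L)
  codes <- unique(normalize_icd10(dx_codes))
  hit <- vapply(weights$prefixes, function(pf) {
    any(outer(codes, pf, startsWith))
  }, logical(1))
  present <- weights$category[hit]
  # severity hierarchy: a present superseder silences its milder partner
  silenced <- weights$supersedes[hit]
  silenced <- silenced[nzchar(silenced)]
  present <- setdiff(present, silenced)
  as.integer(sum(weights$weight[match(present, weights$category)]))
}

#' Attach COCI series and comorbidity scores to a panel set
#'
#' Convenience step used by the pipeline: computes the per-patient upCCI from
#' all diagnosis codes observed in the window and stores it on the patients
#' table.
#'
#' @param panels a `coc_panels` object.
#' @param weights a weight table from [load_upcci_weights()].
#' @return `panels` with an `upcci` column on `panels$patients`.
#' @export
add_upcci <- function(panels, weights = load_upcci_weights()) {
  panels$patients$upcci <- vapply(panels$patients$dx_codes, upcci,
                                  integer(1), weights = weights)
  panels
}
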