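#' Year-on-year growth rates of a mean-expense series
#'
#' growth_t = (mean_t / mean_(t-1) - 1) * 100, rounded half-up to 2 decimals;
#' undefined (NA) for the first year.
#'
#' @param means numeric vector of per-year means.
#' @return numeric vector of the same length (first element `NA`).
#' @export
growth_rates <- function(means) {
  g <- c(NA_real_, 100 * (means[-1] / means[-length(means)] - 1))
  round_half_up(g, 2)
}

#' Annual per-capita expense series
#'
#' Mean total expense per year over all cohort patients (patients with no
#' spending in a year contribute zero), with year-on-year growth rates.
#'
#' @param panels a `coc_panels` object.
#' @return tibble with `year`, `mean_expense`, `growth_pct`.
#' @export
per_capita_series <- function(panels) {
  tab <- panels$years |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(mean_expense = sum(.data$expense_total) /
                       n_patients(panels), .groups = "drop") |>
    dplyr::arrange(.data$year)
  tab$growth_pct <- growth_rates(tab$mean_expense)
  tab
}

#' Trajectory-group shares as percentages
#'
#' @param assignment integer group labels (or anything `table()`-able).
#' @return named numeric vector, 100 * count / total, rounded half-up to 2
#'   decimals.
#' @export
group_proportions <- function(assignment) {
  tab <- table(assignment)
  stats::setNames(round_half_up(100 * as.numeric(tab) / sum(tab), 2),
                  names(tab))
}

#' Per-group, per-year mean expenses
#'
#' @param panels a `coc_panels` object.
#' @param assignment named or ordered integer labels, one per patient in
#'   `panels$patients` order (or a tibble with `patient_id`, `group`).
#' @return tibble with `group`, `year`, `mean_expense` (`NA` for empty
#'   groups).
#' @export
group_annual_means <- function(panels, assignment) {
  asg <- assignment_table(panels, assignment)
  y <- dplyr::inner_join(panels$years, asg, by = "patient_id")
  out <- y |>
    dplyr::group_by(.data$group, .data$year) |>
    dplyr::summarise(mean_expense = mean(.data$expense_total),
                     .groups = "drop")
  tidyr::complete(out, group = sort(unique(asg$group)),
                  year = sort(unique(panels$years$year)))
}

assignment_table <- function(panels, assignment) {
  if (is.data.frame(assignment)) {
    tibble::tibble(patient_id = as.character(assignment$patient_id),
                   group = as.integer(assignment$group))
  } else if (!is.null(names(assignment))) {
    tibble::tibble(patient_id = names(assignment),
                   group = as.integer(assignment))
  } else {
    stopifnot(length(assignment) == n_patients(panels))
    tibble::tibble(patient_id = panels$patients$patient_id,
                   group = as.integer(assignment))
  }
}

# age-group factor used throughout: 19-59 (includes 18-year-old adults),
# 60-74, 75+
age_group <- function(age) {
  cut(age, breaks = c(-Inf, 59, 74, Inf),
      labels = c("19-59", "60-74", "75+"))
}

#' Design matrix for the expense regression
#'
#' Response: the patient's mean annual total expense over the horizon (CNY).
#' Design: intercept; trajectory-group dummies G1..G(K-1) with the highest
#' group (GK, high continuity) as reference; male dummy (female reference);
#' age-group dummies 19-59 and 60-74 (75+ reference); employee-insurance
#' dummy (resident reference); upCCI as a continuous term. Patients with a
#' missing covariate are dropped and counted.
#'
#' @param panels a `coc_panels` object with `sex`, `age_baseline`,
#'   `insurance_type` and `upcci` on the patients table.
#' @param assignment trajectory-group labels (see [group_annual_means()]).
#' @param pooled if `TRUE`, one observation per patient-year (annual expense
#'   as response) instead of one per patient.
#' @return list with `y`, `X` (model matrix), `data` (the analysis tibble)
#'   and `n_dropped`.
#' @export
build_design <- function(panels, assignment, pooled = FALSE) {
  asg <- assignment_table(panels, assignment)
  pts <- dplyr::inner_join(panels$patients, asg, by = "patient_id")
  K <- max(asg$group)

  ann <- panels$years |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(mean_expense = sum(.data$expense_total) /
                       panels$horizon, .groups = "drop")
  df <- dplyr::inner_join(pts, ann, by = "patient_id")
  df <- tibble::tibble(
    patient_id = df$patient_id,
    y = df$mean_expense,
    group = df$group,
    male = as.integer(df$sex == "male"),
    age_grp = age_group(df$age_baseline),
    employee = as.integer(df$insurance_type == "employee"),
    upcci = as.numeric(df$upcci))
  complete <- stats::complete.cases(df)
  n_dropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]

  if (pooled) {
    yy <- dplyr::inner_join(
      panels$years[, c("patient_id", "year", "expense_total")],
      df[setdiff(names(df), "y")], by = "patient_id")
    df <- dplyr::rename(yy, y = "expense_total")
  }

  X <- cbind(`(Intercept)` = rep(1, nrow(df)))
  for (g in seq_len(K - 1L)) {
    X <- cbind(X, as.integer(df$group == g))
    colnames(X)[ncol(X)] <- paste0("G", g)
  }
  X <- cbind(X,
             male = df$male,
             `age19-59` = as.integer(df$age_grp == "19-59"),
             `age60-74` = as.integer(df$age_grp == "60-74"),
             employee = df$employee,
             upcci = df$upcci)
  list(y = df$y, X = X, data = df, n_dropped = n_dropped)
}

#' Ordinary least squares with a classical coefficient table
#'
#' Fits by [stats::lm()] and reports estimates, classical standard errors,
#' t statistics, two-sided p values and 95% confidence intervals.
#'
#' @param y response vector.
#' @param X model matrix including the intercept column.
#' @return an `expense_fit`: list with `coefficients` (tibble: `term`,
#'   `estimate`, `se`, `t`, `p`, `ci_lo`, `ci_hi`), `n`, `r_squared`,
#'   `sigma`, and the underlying `lm` fit.
#' @export
ols_fit <- function(y, X) {
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("need more observations than parameters")
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(y ~ X - 1)
  sm <- summary(fit)
  est <- sm$coefficients
  tcrit <- stats::qt(0.975, df = n - p)
  coefs <- tibble::tibble(
    term = colnames(X),
    estimate = est[, 1L],
    se = est[, 2L],
    t = est[, 3L],
    p = est[, 4L],
    ci_lo = est[, 1L] - tcrit * est[, 2L],
    ci_hi = est[, 1L] + tcrit * est[, 2L])
  structure(list(coefficients = coefs, n = n,
                 r_squared = sm$r.squared, sigma = sm$sigma, lm = fit),
            class = "expense_fit")
}

#' @export
print.expense_fit <- function(x, ...) {
  cat("Expense regression (OLS), n = ", x$n,
      ", R^2 = ", signif(x$r_squared, 4), "\n", sep = "")
  df <- as.data.frame(x$coefficients)
  df[-1] <- lapply(df[-1], signif, 6)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Covariate-adjusted expense regression on trajectory groups
#'
#' One-call wrapper: builds the design with [build_design()] and fits with
#' [ols_fit()].
#'
#' @inheritParams build_design
#' @return an `expense_fit` with the design attached as `design`.
#' @export
expense_regression <- function(panels, assignment, pooled = FALSE) {
  d <- build_design(panels, assignment, pooled = pooled)
  fit <- ols_fit(d$y, d$X)
  fit$design <- d
  fit
}

#' Group characteristics cross-tabs
#'
#' Counts and percentages of sex, age group, insurance type and upCCI level
#' within each trajectory group (column percentages).
#'
#' @inheritParams build_design
#' @return tibble with `variable`, `level`, `group`, `n`, `pct`.
#' @export
group_characteristics <- function(panels, assignment) {
  asg <- assignment_table(panels, assignment)
  pts <- dplyr::inner_join(panels$patients, asg, by = "patient_id")
  cci_lvl <- ifelse(pts$upcci >= 4, ">=4", as.character(pts$upcci))
  long <- dplyr::bind_rows(
    tibble::tibble(variable = "sex", level = pts$sex, group = pts$group),
    tibble::tibble(variable = "age_group",
                   level = as.character(age_group(pts$age_baseline)),
                   group = pts$group),
    tibble::tibble(variable = "insurance", level = pts$insurance_type,
                   group = pts$group),
    tibble::tibble(variable = "upcci", level = cci_lvl, group = pts$group))
  long |>
    dplyr::count(.data$variable, .data$level, .data$group, name = "n") |>
    dplyr::group_by(.data$variable, .data$group) |>
    dplyr::mutate(pct = round_half_up(100 * .data$n / sum(.data$n), 2)) |>
    dplyr::ungroup()
}
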