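#' Pipeline run configuration
#'
#' Bundles every path, threshold and fitting option of a full analysis run.
#' Defaults follow the study conventions: a 6-year window, a per-year minimum
#' of 3 visits, at least 3 qualifying years, adults (18+) at baseline, group
#' shares of at least 5% and AvePP above 0.7.
#'
#' @param claims_path visit-level claims CSV.
#' @param demographics_path patient demographics CSV (`patient_id`, `sex`,
#'   `birth_date`, `insurance_type`).
#' @param out_dir output directory (created if absent).
#' @param baseline_year,horizon observation window.
#' @param min_visits_per_year,min_qualifying_years,adult_age cohort filters.
#' @param k_range,order_set candidate grid (see [enumerate_specs()]).
#' @param n_starts,tol,max_iter,seed EM settings.
#' @param min_share,min_avepp selection thresholds.
#' @param pooled use pooled patient-year observations in the regression.
#' @param schema a [claims_schema()].
#' @param weights_path optional alternative upCCI weight table.
#' @return a `run_config` list.
#' @export
run_config <- function(claims_path, demographics_path = NULL, out_dir,
                       baseline_year = 2016L, horizon = 6L,
                       min_visits_per_year = 3L, min_qualifying_years = 3L,
                       adult_age = 18L,
                       k_range = 2:6, order_set = 1:3,
                       n_starts = 20L, tol = 1e-6, max_iter = 500L,
                       seed = 1L, min_share = 0.05, min_avepp = 0.7,
                       pooled = FALSE, schema = claims_schema(),
                       weights_path = NULL) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full continuity-of-care trajectory analysis
#'
#' Orchestrates ingest, panel building, cohort filtering, COCI and upCCI
#' computation, the candidate model grid, best-model selection, assignment,
#' the descriptive tables, the expense regression, a trajectory plot and a
#' machine-readable manifest. All stages are seeded from `config$seed`, so a
#' rerun with the same config is numerically identical.
#'
#' @param config a [run_config()].
#' @return the output directory, invisibly; side effect: files
#'   `panel_years.csv`, `patients.csv`, `disposition.csv`, `ledger.csv`,
#'   `chosen_model.json`, `assignments.csv`, `table_annual_expenses.csv`,
#'   `table_group_characteristics.csv`, `table_group_annual_means.csv`,
#'   `table_regression.csv`, `trajectories.png` and `manifest.json` under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$claims_path)) {
    stop("claims file not found: ", config$claims_path)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("coctraj")),
                   thresholds = list(
                     min_visits_per_year = config$min_visits_per_year,
                     min_qualifying_years = config$min_qualifying_years,
                     adult_age = config$adult_age,
                     min_share = config$min_share,
                     min_avepp = config$min_avepp))
  stage <- "ingest"
  on.exit({
    manifest$failed_at <- stage
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  visits <- read_claims(config$claims_path, config$schema)
  manifest$n_claim_lines <- attr(visits, "n_lines_in")
  manifest$n_visits <- nrow(visits)

  stage <- "panels"
  demo <- if (!is.null(config$demographics_path)) {
    d <- utils::read.csv(config$demographics_path, stringsAsFactors = FALSE,
                         colClasses = "character")
    d$birth_date <- as.Date(d$birth_date)
    d
  } else NULL
  panels <- build_panels(visits, demo, config$baseline_year, config$horizon)
  manifest$n_visits_outside_window <- attr(panels, "n_visits_outside_window")
  manifest$patients_in <- n_patients(panels)

  stage <- "cohort_filter"
  panels <- cohort_filter(panels, config$min_visits_per_year,
                          config$min_qualifying_years, config$adult_age)
  disposition <- attr(panels, "disposition")
  manifest$patients_kept <- n_patients(panels)
  manifest$exclusions <- as.list(table(disposition$reason))
  utils::write.csv(disposition, file.path(config$out_dir, "disposition.csv"),
                   row.names = FALSE)

  stage <- "indices"
  weights <- load_upcci_weights(config$weights_path)
  panels <- add_upcci(panels, weights)
  ptab <- panel_table(panels, config$min_visits_per_year)
  utils::write.csv(ptab, file.path(config$out_dir, "panel_years.csv"),
                   row.names = FALSE)
  pts_out <- panels$patients[setdiff(names(panels$patients), "dx_codes")]
  utils::write.csv(pts_out, file.path(config$out_dir, "patients.csv"),
                   row.names = FALSE)

  stage <- "grid"
  Y <- coci_matrix(panels, config$min_visits_per_year)
  specs <- enumerate_specs(config$k_range, config$order_set)
  grid <- run_grid(Y, specs, n_starts = config$n_starts, seed = config$seed,
                   tol = config$tol, max_iter = config$max_iter,
                   min_share = config$min_share, min_avepp = config$min_avepp)

  stage <- "selection"
  sel <- select_best(grid, config$min_share, config$min_avepp)
  utils::write.csv(sel$ledger, file.path(config$out_dir, "ledger.csv"),
                   row.names = FALSE)
  if (is.null(sel$chosen)) {
    manifest$chosen <- NULL
    stage <- "no_passing_model"
    stop("no candidate model satisfies the selection constraints")
  }
  idx <- which(sel$ledger$chosen)
  fit <- fit_gbtm(Y, specs[[idx]], n_starts = config$n_starts,
                  seed = derive_seed(config$seed, idx),
                  tol = config$tol, max_iter = config$max_iter)
  manifest$chosen <- list(k = fit$spec$k, orders = fit$spec$orders,
                          bic = fit$bic, loglik = fit$loglik)
  write_gbtm_json(fit, file.path(config$out_dir, "chosen_model.json"))
  asg <- tibble::tibble(patient_id = fit$patient_id,
                        group = fit$assignment,
                        max_posterior = apply(fit$posteriors, 1L, max))
  utils::write.csv(asg, file.path(config$out_dir, "assignments.csv"),
                   row.names = FALSE)

  stage <- "tables"
  t1 <- per_capita_series(panels)
  utils::write.csv(t1, file.path(config$out_dir, "table_annual_expenses.csv"),
                   row.names = FALSE)
  t3 <- group_characteristics(panels, asg)
  utils::write.csv(t3, file.path(config$out_dir,
                                 "table_group_characteristics.csv"),
                   row.names = FALSE)
  t4 <- group_annual_means(panels, asg)
  utils::write.csv(t4, file.path(config$out_dir,
                                 "table_group_annual_means.csv"),
                   row.names = FALSE)

  stage <- "regression"
  reg <- expense_regression(panels, asg, pooled = config$pooled)
  utils::write.csv(reg$coefficients,
                   file.path(config$out_dir, "table_regression.csv"),
                   row.names = FALSE)
  manifest$regression <- list(n = reg$n, r_squared = reg$r_squared)

  stage <- "plot"
  plot_ok <- tryCatch({
    p <- plot_trajectories(fit, baseline_year = config$baseline_year)
    ggplot2::ggsave(file.path(config$out_dir, "trajectories.png"), p,
                    width = 7, height = 5, dpi = 150)
    TRUE
  }, error = function(e) FALSE)
  manifest$plot_written <- plot_ok

  stage <- "done"
  manifest$failed_at <- NULL
  on.exit()
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
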