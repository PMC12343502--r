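#' Simulation configuration
#'
#' Defines a synthetic cohort with known trajectory-group structure. The
#' default preset emulates the study population the package targets: four
#' COCI trajectory groups over six annual windows — low-level maintenance
#' (the majority), low-level increase, high-level decrease, high-level
#' maintenance — with expense levels ordered G1 > G3 > G2 > G4 and a
#' G1-vs-G4 gap of 3,000 CNY under reference covariates.
#'
#' @param n_patients cohort size.
#' @param horizon number of annual windows T (default 6).
#' @param baseline_year first calendar year (default 2016).
#' @param pi_true group membership probabilities (sum 1).
#' @param beta_true list of per-group coefficient vectors on the scaled-time
#'   basis (1, s, ..., s^order), s = t/(T-1).
#' @param sigma_true residual SD of the latent COCI around the group mean.
#' @param missing_year_rate probability a patient-year falls below the visit
#'   minimum (contributing a missing COCI).
#' @param visit_lambda observed-year visit counts are 3 + Poisson(lambda).
#' @param expense_base per-group mean annual expense (CNY) under reference
#'   covariates (female, 75+, resident insurance, upCCI 0).
#' @param expense_effects additive mean shifts: `male`, `age_19_59`,
#'   `age_60_74`, `employee`, and `upcci` (per point).
#' @param expense_sdlog SD of the multiplicative lognormal expense noise
#'   (mean-preserving).
#' @param p_male,p_age,p_employee demographic mix; `p_age` is the probability
#'   vector over age groups 19-59 / 60-74 / 75+ at baseline.
#' @param p_cci probability vector over upCCI scores 0..4.
#' @param seed RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_patients = 2000L,
                       horizon = 6L,
                       baseline_year = 2016L,
                       pi_true = c(0.52, 0.17, 0.19, 0.12),
                       beta_true = list(
                         c(0.45, -0.10, 0.10),            # flat-low ~0.4-0.5
                         c(0.50, 0.55, -0.90, 0.65),      # low rising to ~0.8
                         c(0.88, -0.60, 0.75, -0.55),     # high falling
                         c(0.85, 0.10, -0.30, 0.25)),     # flat-high ~0.85
                       sigma_true = 0.10,
                       missing_year_rate = 0.10,
                       visit_lambda = 5,
                       expense_base = NULL,
                       expense_effects = c(male = 450, age_19_59 = -4000,
                                           age_60_74 = -2200, employee = 3500,
                                           upcci = 2300),
                       expense_sdlog = 0.5,
                       p_male = 0.514,
                       p_age = c(0.2876, 0.4550, 0.2574),
                       p_employee = 0.441,
                       p_cci = c(0.530, 0.372, 0.0547, 0.0361, 0.0072),
                       seed = 1L) {
  if (is.null(expense_base)) {
    # default ordering for K = 4 (G1 > G3 > G2 > G4); otherwise a
    # decreasing gradient from low- to high-continuity groups
    expense_base <- if (length(pi_true) == 4L) c(7300, 5300, 6100, 4300)
      else seq(7300, 4300, length.out = length(pi_true))
  }
  stopifnot(abs(sum(pi_true) - 1) < 1e-8, sigma_true > 0,
            missing_year_rate >= 0, missing_year_rate <= 1,
            length(beta_true) == length(pi_true),
            length(expense_base) == length(pi_true))
  structure(as.list(environment()), class = "sim_config")
}

# per-group latent mean trajectories implied by a config (T x K)
sim_group_means <- function(config) {
  vapply(config$beta_true, function(b) {
    drop(design_basis(length(b) - 1L, config$horizon) %*% b)
  }, numeric(config$horizon))
}

#' Simulate COCI panels with known group labels
#'
#' Fast path for trajectory-model testing: draws each patient's group from
#' `pi_true`, then per observed year draws y ~ N(x_t' beta_g, sigma^2)
#' censored to \[0, 1\]; years are marked missing independently at
#' `missing_year_rate` (every patient keeps at least one observed year).
#'
#' @param config a [sim_config()].
#' @return list with `Y` (patients x years matrix, `NA` = missing), `labels`
#'   (true groups) and `config`.
#' @export
simulate_coci_panel <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_patients; T <- config$horizon
  K <- length(config$pi_true)
  labels <- sample.int(K, n, replace = TRUE, prob = config$pi_true)
  mu <- sim_group_means(config)              # T x K
  Y <- matrix(stats::rnorm(n * T, mean = t(mu[, labels]),
                           sd = config$sigma_true), n, T, byrow = FALSE)
  Y <- pmin(pmax(Y, 0), 1)
  miss <- matrix(stats::runif(n * T) < config$missing_year_rate, n, T)
  # keep at least one observed year per patient
  all_missing <- rowSums(!miss) == 0L
  miss[all_missing, 1L] <- FALSE
  Y[miss] <- NA_real_
  rownames(Y) <- sprintf("P%05d", seq_len(n))
  list(Y = Y, labels = labels, config = config)
}

#' Provider sequence achieving a target COCI
#'
#' Builds a year's visit sequence whose concentration is as close as possible
#' to a target COCI among tallies of the form "n1 visits to one provider, the
#' rest to distinct providers": n1 is chosen to minimize
#' |n1(n1-1)/(N(N-1)) - target|. Visit order is randomized.
#'
#' @param target desired COCI in \[0, 1\].
#' @param n_visits total visits N (>= 2).
#' @param seed RNG seed for the shuffle.
#' @return character vector of provider ids of length `n_visits`; attribute
#'   `achieved` carries the realized COCI.
#' @export
visits_from_coci <- function(target, n_visits, seed = 1L) {
  if (n_visits < 2L) stop("need at least 2 visits")
  if (target < 0 || target > 1) stop("target must lie in [0, 1]")
  n1 <- 1:n_visits
  achievable <- n1 * (n1 - 1) / (n_visits * (n_visits - 1))
  best <- which.min(abs(achievable - target))
  ids <- c(rep("H1", best),
           if (best < n_visits) paste0("H", 1 + seq_len(n_visits - best)))
  set.seed(seed)
  out <- sample(ids)
  attr(out, "achieved") <- achievable[best]
  out
}

#' Simulate a visit-level claims cohort with ground truth
#'
#' Composes [simulate_coci_panel()] and [visits_from_coci()] into claim
#' lines: per observed patient-year, 3 + Poisson(`visit_lambda`) visits on
#' distinct dates spread through the year, with a provider mix matching the
#' simulated COCI; missing-COCI years get 1-2 visits (below the minimum). Every patient carries a
#' hypertension primary code (I10) on most visits; comorbidity codes drawn
#' from `p_cci` are placed on later visits so the recovered upCCI equals the
#' drawn score. Annual expense totals follow the per-group expense model with
#' covariate shifts and mean-preserving lognormal noise, split randomly over
#' the year's visits.
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given, writes `claims.csv`,
#'   `demographics.csv` and `truth.csv` there.
#' @return list with `claims` (visit tibble), `demographics`, `truth`
#'   (patient-level: label, eligibility, upCCI score), `truth_years`
#'   (patient-year: target vs achievable COCI, expense total) and `config`.
#' @export
simulate_claims <- function(config = sim_config(), dir = NULL) {
  panel <- simulate_coci_panel(config)
  set.seed(derive_seed(config$seed, 7919L))
  n <- config$n_patients; T <- config$horizon
  ids <- rownames(panel$Y)

  sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
  agegrp <- sample.int(3L, n, replace = TRUE, prob = config$p_age)
  age <- ifelse(agegrp == 1L, sample(19:59, n, replace = TRUE),
         ifelse(agegrp == 2L, sample(60:74, n, replace = TRUE),
                sample(75:95, n, replace = TRUE)))
  birth_year <- config$baseline_year - age
  insurance <- ifelse(stats::runif(n) < config$p_employee,
                      "employee", "resident")
  cci_score <- sample(0:4, n, replace = TRUE, prob = config$p_cci)
  # comorbidity code bundles realizing each upCCI score under the packaged
  # weight table (J44* chronic pulmonary = 1, I50* CHF = 2, N18* renal = 1)
  cci_codes <- list(character(0), "J449", "I509", c("I509", "J449"),
                    c("I509", "J449", "N189"))

  mu_expense <- config$expense_base[panel$labels] +
    config$expense_effects[["male"]] * (sex == "male") +
    config$expense_effects[["age_19_59"]] * (agegrp == 1L) +
    config$expense_effects[["age_60_74"]] * (agegrp == 2L) +
    config$expense_effects[["employee"]] * (insurance == "employee") +
    config$expense_effects[["upcci"]] * cci_score
  if (any(mu_expense <= 0)) stop("expense model implies non-positive means")

  rows <- vector("list", n)
  truth_years <- vector("list", n)
  eligible <- logical(n)
  for (i in seq_len(n)) {
    obs_years <- which(!is.na(panel$Y[i, ]))
    eligible[i] <- length(obs_years) >= 3L
    extra_dx <- cci_codes[[cci_score[i] + 1L]]
    pr <- list(); ty <- vector("list", T)
    for (t in seq_len(T) - 1L) {
      year <- config$baseline_year + t
      observed <- (t + 1L) %in% obs_years
      if (observed) {
        nv <- 3L + stats::rpois(1L, config$visit_lambda)
        target <- panel$Y[i, t + 1L]
        prov <- visits_from_coci(target, nv,
                                 seed = derive_seed(config$seed, i * 101L + t))
        achieved <- attr(prov, "achieved")
        prov <- as.character(prov)
      } else {
        # a missing-COCI year is one below the visit minimum, not visit-free
        nv <- sample(1:2, 1L)
        prov <- if (nv > 0L) paste0("H", seq_len(nv)) else character(0)
        achieved <- NA_real_
        target <- NA_real_
      }
      expense_total <- if (nv > 0L) {
        mu_expense[i] * stats::rlnorm(1L, -config$expense_sdlog^2 / 2,
                                      config$expense_sdlog)
      } else 0
      if (nv > 0L) {
        days <- sort(sample.int(360L, nv))
        split <- stats::runif(nv)
        split <- split / sum(split) * expense_total
        dx <- rep("I10", nv)
        if (length(extra_dx) && nv > 1L) {
          slots <- utils::tail(seq_len(nv), min(length(extra_dx), nv - 1L))
          dx[slots] <- extra_dx[seq_along(slots)]
        }
        pr[[length(pr) + 1L]] <- tibble::tibble(
          patient_id = ids[i],
          visit_date = as.Date(sprintf("%d-01-01", year)) + days,
          provider_id = paste0(ids[i], "_", prov),
          primary_dx = dx,
          expense = round(split, 2),
          insurance_type = insurance[i])
      }
      ty[[t + 1L]] <- tibble::tibble(
        patient_id = ids[i], t = t, year = year, n_visits = nv,
        coci_target = target, coci_achieved = achieved,
        expense_total = if (nv > 0L) sum(round(split, 2)) else 0)
    }
    rows[[i]] <- dplyr::bind_rows(pr)
    truth_years[[i]] <- dplyr::bind_rows(ty)
  }
  claims <- dplyr::bind_rows(rows)
  truth_years <- dplyr::bind_rows(truth_years)
  demographics <- tibble::tibble(
    patient_id = ids, sex = sex,
    birth_date = as.Date(sprintf("%d-06-30", birth_year)),
    insurance_type = insurance)
  truth <- tibble::tibble(
    patient_id = ids, label = panel$labels, eligible = eligible,
    upcci_true = cci_score, age_baseline = age,
    mean_expense_true = mu_expense)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(claims, file.path(dir, "claims.csv"), row.names = FALSE)
    utils::write.csv(demographics, file.path(dir, "demographics.csv"),
                     row.names = FALSE)
    utils::write.csv(dplyr::left_join(truth, truth_years, by = "patient_id"),
                     file.path(dir, "truth.csv"), row.names = FALSE)
  }
  list(claims = claims, demographics = demographics, truth = truth,
       truth_years = truth_years, config = config)
}
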