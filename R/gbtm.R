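#' Trajectory model specification
#'
#' A candidate group-based trajectory model: the number of latent groups K
#' and one polynomial order per group (1 = linear, 2 = quadratic, 3 = cubic)
#' for the group's mean trajectory over scaled time.
#'
#' @param orders integer vector of length K, each in 1..3.
#' @return a `trajectory_spec` object.
#' @export
trajectory_spec <- function(orders) {
  orders <- as.integer(orders)
  if (length(orders) < 1L || any(orders < 1L | orders > 3L)) {
    stop("orders must be a vector of polynomial orders in 1..3")
  }
  structure(list(k = length(orders), orders = orders),
            class = "trajectory_spec")
}

#' @export
format.trajectory_spec <- function(x, ...) {
  sprintf("%d groups (%s)", x$k, paste(x$orders, collapse = ","))
}

#' @export
print.trajectory_spec <- function(x, ...) {
  cat("<trajectory_spec> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Polynomial basis row at one time point
#'
#' Time is scaled to s = t/(T-1) in \[0, 1\] for numerical conditioning; the
#' basis is (1, s, ..., s^order).
#'
#' @param t year index, 0..T-1.
#' @param order polynomial order in 1..3.
#' @param T number of time points.
#' @return numeric vector of length `order + 1`.
#' @export
design_row <- function(t, order, T) {
  if (!order %in% 1:3) stop("order must be in 1..3")
  if (t < 0 || t > T - 1) stop("t must be in 0..T-1")
  s <- t / (T - 1)
  s^(0:order)
}

# T x (order+1) basis matrix over all time points
design_basis <- function(order, T) {
  s <- (0:(T - 1)) / (T - 1)
  outer(s, 0:order, `^`)
}

#' Censored-normal log-density on \[0, 1\]
#'
#' The outcome is modelled as a latent normal observed only inside the unit
#' interval: values at the bounds are censored, with point masses given by
#' the normal CDF beyond the limit. Interior y gives the usual normal
#' log-density; y = 0 gives log P(latent <= 0); y = 1 gives
#' log P(latent >= 1).
#'
#' @param y observed values in \[0, 1\] (vectorized).
#' @param mu latent mean(s).
#' @param sigma latent standard deviation (> 0).
#' @return log-density/log-mass vector.
#' @export
cnorm_logdensity <- function(y, mu, sigma) {
  if (any(y < 0 | y > 1, na.rm = TRUE)) stop("y must lie in [0, 1]")
  if (sigma <= 0) stop("sigma must be positive")
  out <- stats::dnorm(y, mu, sigma, log = TRUE)
  lo <- !is.na(y) & y <= 0
  hi <- !is.na(y) & y >= 1
  if (any(lo)) {
    mlo <- if (length(mu) > 1) mu[lo] else mu
    out[lo] <- stats::pnorm((0 - mlo) / sigma, log.p = TRUE)
  }
  if (any(hi)) {
    mhi <- if (length(mu) > 1) mu[hi] else mu
    out[hi] <- stats::pnorm((1 - mhi) / sigma, lower.tail = FALSE, log.p = TRUE)
  }
  out
}

# Per-patient, per-group log-likelihood matrix (n x K). Y is the n x T COCI
# matrix with NA for missing years; missing years simply drop out of the sum.
component_loglik <- function(Y, mu_mat, sigma) {
  n <- nrow(Y); K <- ncol(mu_mat); T <- ncol(Y)
  obs <- !is.na(Y)
  la <- matrix(0, n, K)
  for (g in seq_len(K)) {
    M <- matrix(mu_mat[, g], n, T, byrow = TRUE)
    ld <- matrix(0, n, T)
    ld[obs] <- cnorm_logdensity(Y[obs], M[obs], sigma)
    la[, g] <- rowSums(ld)
  }
  la
}

#' Mixture log-likelihood of a censored-normal GBTM
#'
#' sum_i log sum_g pi_g prod_t f_cnorm(y_it | x_t' beta_g, sigma), with
#' missing years skipped.
#'
#' @param Y patients x years matrix of COCI values (`NA` = missing).
#' @param spec a [trajectory_spec()].
#' @param pi mixing proportions (length K, positive, sum 1).
#' @param beta list of K coefficient vectors on the scaled-time basis.
#' @param sigma shared residual SD.
#' @return log-likelihood scalar.
#' @export
gbtm_loglik <- function(Y, spec, pi, beta, sigma) {
  if (any(pi <= 0)) stop("mixing proportions must be positive")
  mu <- group_means(spec, beta, ncol(Y))
  la <- component_loglik(Y, mu, sigma)
  sum(row_logsumexp(sweep(la, 2L, log(pi), `+`)))
}

# T x K matrix of group mean trajectories
group_means <- function(spec, beta, T) {
  vapply(seq_len(spec$k), function(g) {
    drop(design_basis(spec$orders[g], T) %*% beta[[g]])
  }, numeric(T))
}

#' Posterior group-membership probabilities
#'
#' P(g | Y_i) proportional to pi_g times the product of the patient's
#' observed-year censored-normal densities under group g; computed in log
#' space.
#'
#' @inheritParams gbtm_loglik
#' @return n x K matrix, rows summing to 1.
#' @export
gbtm_posteriors <- function(Y, spec, pi, beta, sigma) {
  if (any(rowSums(!is.na(Y)) == 0L)) {
    stop("every patient must have at least one observed year")
  }
  mu <- group_means(spec, beta, ncol(Y))
  la <- sweep(component_loglik(Y, mu, sigma), 2L, log(pi), `+`)
  exp(la - row_logsumexp(la))
}

#' Trajectory-model BIC (trajectory-macro convention)
#'
#' BIC = loglik - (k/2) log(n) with n the number of patients and k the free
#' parameter count: sum_g (order_g + 1) polynomial coefficients, K - 1 mixing
#' proportions, and one residual SD. Values are negative, with values closer
#' to 0 indicating better fit.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters (see [gbtm_n_params()]).
#' @param n number of patients.
#' @return BIC value.
#' @export
gbtm_bic <- function(loglik, k, n) loglik - (k / 2) * log(n)

#' Free-parameter count of a trajectory spec
#' @param spec a [trajectory_spec()].
#' @return integer.
#' @export
gbtm_n_params <- function(spec) {
  as.integer(sum(spec$orders + 1L) + (spec$k - 1L) + 1L)
}

#' Average posterior probability by assigned group
#'
#' For each group, the mean posterior membership probability among the
#' patients assigned to it; a classification-sharpness diagnostic,
#' conventionally acceptable above 0.7. `NA` for empty groups.
#'
#' @param posteriors n x K posterior matrix.
#' @param assignment integer group labels (argmax of each posterior row).
#' @return numeric vector of length K.
#' @export
avepp <- function(posteriors, assignment) {
  K <- ncol(posteriors)
  vapply(seq_len(K), function(g) {
    idx <- assignment == g
    if (!any(idx)) NA_real_ else mean(posteriors[idx, g])
  }, numeric(1))
}

# E[latent] and E[latent^2] given the observed (possibly censored) value.
# Interior cells are exact; censored cells use truncated-normal moments.
cnorm_moments <- function(y, mu, sigma) {
  e1 <- y
  e2 <- y^2
  lo <- y <= 0
  hi <- y >= 1
  if (any(lo)) {
    a <- (0 - mu[lo]) / sigma
    lam <- exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, log.p = TRUE))
    e1[lo] <- mu[lo] - sigma * lam
    e2[lo] <- mu[lo]^2 + sigma^2 - sigma * lam * (0 + mu[lo])
  }
  if (any(hi)) {
    a <- (1 - mu[hi]) / sigma
    lam <- exp(stats::dnorm(a, log = TRUE) -
                 stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
    e1[hi] <- mu[hi] + sigma * lam
    e2[hi] <- mu[hi]^2 + sigma^2 + sigma * lam * (1 + mu[hi])
  }
  list(e1 = e1, e2 = e2)
}

# One EM run from a given starting point. Returns params, loglik trace and a
# convergence flag. The complete-data model has two layers of latency (group
# membership and the censored latent outcome); both E-steps are closed form,
# and the joint M-step is a weighted least-squares update per group plus a
# pooled variance update, so the observed-data log-likelihood ascends.
em_run <- function(Y, spec, pi, beta, sigma, tol, max_iter, sigma_min) {
  n <- nrow(Y); T <- ncol(Y); K <- spec$k
  obs <- !is.na(Y)
  bases <- lapply(spec$orders, design_basis, T = T)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    mu_mat <- group_means(spec, beta, T)
    la <- sweep(component_loglik(Y, mu_mat, sigma), 2L, log(pi), `+`)
    lse <- row_logsumexp(la)
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    w <- exp(la - lse)  # n x K responsibilities

    pi <- pmax(colMeans(w), 1e-10)
    pi <- pi / sum(pi)

    ss_num <- 0
    ss_den <- 0
    for (g in seq_len(K)) {
      M <- matrix(mu_mat[, g], n, T, byrow = TRUE)
      E1 <- matrix(0, n, T); E2 <- matrix(0, n, T)
      mom <- cnorm_moments(Y[obs], M[obs], sigma)
      E1[obs] <- mom$e1
      E2[obs] <- mom$e2
      W <- w[, g] * obs  # cell weights
      ct <- colSums(W)
      Xb <- bases[[g]]
      A <- crossprod(Xb, Xb * ct)
      b <- crossprod(Xb, colSums(W * E1))
      beta[[g]] <- drop(solve(A + diag(1e-10, ncol(Xb)), b))
      mu_new <- matrix(drop(Xb %*% beta[[g]]), n, T, byrow = TRUE)
      ss_num <- ss_num + sum(W * (E2 - 2 * E1 * mu_new + mu_new^2))
      ss_den <- ss_den + sum(W)
    }
    sigma_new <- sqrt(ss_num / ss_den)
    if (sigma_new < sigma_min) {
      warning("residual SD floored at ", sigma_min)
      sigma_new <- sigma_min
    }
    sigma <- sigma_new
  }
  list(pi = pi, beta = beta, sigma = sigma, loglik = trace[length(trace)],
       trace = trace, converged = converged, n_iter = length(trace))
}

# Starting values: rank patients by mean observed COCI, split into K blocks,
# fit per-block polynomial least squares, jitter coefficients per start.
gbtm_init <- function(Y, spec, jitter_sd = 0.05) {
  n <- nrow(Y); T <- ncol(Y); K <- spec$k
  pmean <- rowMeans(Y, na.rm = TRUE)
  block <- if (K == 1L) rep(1L, n) else
    cut(rank(pmean, ties.method = "first"),
        breaks = K, labels = FALSE, include.lowest = TRUE)
  beta <- vector("list", K)
  resid_ss <- 0; resid_n <- 0
  for (g in seq_len(K)) {
    idx <- which(block == g)
    Yg <- Y[idx, , drop = FALSE]
    obs <- which(!is.na(Yg), arr.ind = TRUE)
    Xb <- design_basis(spec$orders[g], T)
    X <- Xb[obs[, 2L], , drop = FALSE]
    y <- Yg[obs]
    fit <- stats::lm.fit(X, y)
    beta[[g]] <- unname(fit$coefficients) +
      stats::rnorm(ncol(Xb), 0, jitter_sd)
    resid_ss <- resid_ss + sum(fit$residuals^2)
    resid_n <- resid_n + length(y)
  }
  list(pi = rep(1 / K, K), beta = beta,
       sigma = max(sqrt(resid_ss / max(resid_n, 1L)), 0.02))
}

#' Fit a censored-normal group-based trajectory model
#'
#' Maximum-likelihood fit by EM with multiple random starts. Each start
#' initializes from a quantile split of patient-mean COCI with jittered
#' per-block least-squares coefficients; the best converged start (highest
#' log-likelihood) is kept. Groups are relabelled in ascending order of their
#' time-averaged mean trajectory so labels are stable across starts. Patients
#' are assigned to the group with the highest posterior probability (ties to
#' the lowest group index).
#'
#' @param Y patients x years COCI matrix (`NA` = missing year), or a
#'   `coc_panels` object (converted with [coci_matrix()]).
#' @param spec a [trajectory_spec()].
#' @param n_starts number of EM starts (default 20).
#' @param seed RNG seed for the start jitter.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per start.
#' @param sigma_min floor for the residual SD.
#' @param init optional list(pi, beta, sigma) to use as the single start
#'   (bypasses the multi-start scheme; used for reproducing a fit).
#' @return a `gbtm_fit` object with elements `spec`, `pi`, `beta`, `sigma`,
#'   `loglik`, `bic`, `n_params`, `posteriors`, `assignment`, `group_shares`,
#'   `avepp`, `converged`, `n_starts_used`, `trace` (log-likelihood trace of
#'   the winning start), `n`, `T`, `patient_id`.
#' @export
fit_gbtm <- function(Y, spec, n_starts = 20L, seed = 1L, tol = 1e-6,
                     max_iter = 500L, sigma_min = 1e-4, init = NULL) {
  if (inherits(Y, "coc_panels")) Y <- coci_matrix(Y)
  Y <- as.matrix(Y)
  keep <- rowSums(!is.na(Y)) > 0L
  if (!all(keep)) Y <- Y[keep, , drop = FALSE]
  n <- nrow(Y)
  if (n < spec$k * 5L) {
    stop("need at least 5 patients per group (", spec$k * 5L, "), got ", n)
  }

  best <- NULL
  best_any <- NULL
  if (!is.null(init)) {
    run <- em_run(Y, spec, init$pi, init$beta, init$sigma,
                  tol, max_iter, sigma_min)
    best_any <- run
    if (run$converged) best <- run
    starts_used <- 1L
  } else {
    starts_used <- 0L
    for (s in seq_len(n_starts)) {
      set.seed(derive_seed(seed, s))
      st <- gbtm_init(Y, spec)
      run <- tryCatch(
        em_run(Y, spec, st$pi, st$beta, st$sigma, tol, max_iter, sigma_min),
        error = function(e) NULL)
      if (is.null(run)) next
      starts_used <- starts_used + 1L
      if (is.null(best_any) || run$loglik > best_any$loglik) best_any <- run
      if (run$converged && (is.null(best) || run$loglik > best$loglik)) {
        best <- run
      }
    }
  }
  if (is.null(best)) {
    cond <- simpleError("no EM start converged")
    cond$best_state <- best_any
    stop(cond)
  }

  # stable labels: ascending time-averaged mean trajectory
  mu <- group_means(spec, best$beta, ncol(Y))
  ord <- order(colMeans(mu))
  spec_out <- trajectory_spec(spec$orders[ord])
  pi <- best$pi[ord]
  beta <- best$beta[ord]

  post <- gbtm_posteriors(Y, spec_out, pi, beta, best$sigma)
  assignment <- max.col(post, ties.method = "first")
  shares <- tabulate(assignment, nbins = spec$k) / n
  k <- gbtm_n_params(spec_out)

  structure(list(
    spec = spec_out, pi = pi, beta = beta, sigma = best$sigma,
    loglik = best$loglik, n_params = k,
    bic = gbtm_bic(best$loglik, k, n),
    posteriors = post, assignment = assignment,
    group_shares = shares, avepp = avepp(post, assignment),
    converged = best$converged, n_starts_used = starts_used,
    trace = best$trace, n = n, T = ncol(Y),
    patient_id = rownames(Y) %||% as.character(seq_len(n))),
    class = "gbtm_fit")
}

#' @export
print.gbtm_fit <- function(x, digits = 3, ...) {
  cat("Censored-normal group-based trajectory model\n")
  cat("  ", format(x$spec), ", n = ", x$n, ", T = ", x$T, "\n", sep = "")
  cat("  logLik ", format(x$loglik, digits = 8),
      "  BIC ", format(x$bic, digits = 8),
      "  (k = ", x$n_params, ")\n", sep = "")
  cat("  sigma ", signif(x$sigma, digits), "\n", sep = "")
  tab <- data.frame(group = seq_len(x$spec$k),
                    order = x$spec$orders,
                    pi = signif(x$pi, digits),
                    share = signif(x$group_shares, digits),
                    AvePP = signif(x$avepp, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Fitted mean trajectories
#'
#' @param fit a `gbtm_fit`.
#' @return tibble with columns `group`, `t`, `year_index`, `mean` (the fitted
#'   latent mean) and `mean_censored` (clamped to \[0, 1\], the expected
#'   observed scale).
#' @export
trajectory_means <- function(fit) {
  mu <- group_means(fit$spec, fit$beta, fit$T)
  tibble::tibble(
    group = rep(seq_len(fit$spec$k), each = fit$T),
    t = rep(0:(fit$T - 1L), fit$spec$k),
    mean = as.vector(mu),
    mean_censored = pmin(pmax(as.vector(mu), 0), 1))
}

#' Plot fitted group trajectories
#'
#' @param fit a `gbtm_fit`.
#' @param baseline_year optional first calendar year for the x axis.
#' @return a ggplot object.
#' @export
plot_trajectories <- function(fit, baseline_year = NULL) {
  tm <- trajectory_means(fit)
  tm$x <- if (is.null(baseline_year)) tm$t else tm$t + baseline_year
  lab <- sprintf("G%d (%.1f%%)", seq_len(fit$spec$k),
                 100 * fit$group_shares)
  tm$group_lab <- factor(lab[tm$group], levels = lab)
  ggplot2::ggplot(tm, ggplot2::aes(x = .data$x, y = .data$mean_censored,
                                   colour = .data$group_lab)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = if (is.null(baseline_year)) "years since baseline"
                  else "year",
                  y = "Continuity of Care Index",
                  colour = "trajectory group") +
    ggplot2::theme_minimal()
}

#' Serialize a fitted model to JSON
#'
#' @param fit a `gbtm_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gbtm_json <- function(fit, path) {
  doc <- list(
    k = fit$spec$k, orders = fit$spec$orders,
    pi = fit$pi, beta = fit$beta, sigma = fit$sigma,
    loglik = fit$loglik, bic = fit$bic, n_params = fit$n_params,
    n = fit$n, T = fit$T,
    group_shares = fit$group_shares, avepp = fit$avepp,
    converged = fit$converged, n_starts_used = fit$n_starts_used)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
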