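test_that("polynomial basis uses scaled time", {
  expect_equal(design_row(0, 3, 6), c(1, 0, 0, 0))
  expect_equal(design_row(5, 2, 6), c(1, 1, 1))
  expect_equal(design_row(2, 1, 6), c(1, 0.4))
  expect_error(design_row(0, 4, 6), "order")
})

test_that("censored-normal log-density matches closed forms and a numeric CDF oracle", {
  # normal density at its mode
  expect_equal(cnorm_logdensity(0.5, 0.5, 0.1),
               log(1 / (0.1 * sqrt(2 * pi))), tolerance = 1e-9)
  expect_equal(cnorm_logdensity(0.5, 0.5, 0.1), 1.3836466, tolerance = 1e-6)
  # left-censored mass: log P(Z <= -2), against numeric integration
  num <- log(stats::integrate(stats::dnorm, -Inf, -2)$value)
  expect_equal(cnorm_logdensity(0, 0.5, 0.25), num, tolerance = 1e-7)
  expect_equal(cnorm_logdensity(0, 0.5, 0.25), -3.7831843, tolerance = 1e-6)
  # right-censored at the mean: mass one half
  expect_equal(cnorm_logdensity(1, 1.0, 0.1), log(0.5), tolerance = 1e-12)
  expect_error(cnorm_logdensity(1.2, 0.5, 0.1), "0, 1")
  expect_error(cnorm_logdensity(0.5, 0.5, 0), "sigma")
})

test_that("mixture log-likelihood reduces and collapses as expected, and matches brute force", {
  spec1 <- trajectory_spec(1)
  Y <- matrix(c(0.2, 0.4, 0.0, 0.5, 1.0, 0.8), nrow = 3, byrow = TRUE)
  b <- list(c(0.3, 0.2))
  ll1 <- gbtm_loglik(Y, spec1, 1, b, 0.15)
  # two identical components with pi = (0.5, 0.5) collapse to K = 1
  ll2 <- gbtm_loglik(Y, trajectory_spec(c(1, 1)), c(0.5, 0.5),
                     list(b[[1]], b[[1]]), 0.15)
  expect_equal(ll2, ll1, tolerance = 1e-10)

  # brute-force arithmetic over the 12 density terms, K = 2
  pi2 <- c(0.6, 0.4)
  b2 <- list(c(0.3, 0.2), c(0.7, -0.1))
  sig <- 0.15
  dens <- function(y, mu) {
    if (y <= 0) pnorm(0, mu, sig) else
      if (y >= 1) pnorm(1, mu, sig, lower.tail = FALSE) else
        dnorm(y, mu, sig)
  }
  expected <- 0
  for (i in 1:3) {
    terms <- numeric(2)
    for (g in 1:2) {
      mu <- c(b2[[g]][1], sum(b2[[g]]))  # basis at t = 0 and t = T-1 = 1
      terms[g] <- pi2[g] * dens(Y[i, 1], mu[1]) * dens(Y[i, 2], mu[2])
    }
    expected <- expected + log(sum(terms))
  }
  expect_equal(gbtm_loglik(Y, trajectory_spec(c(1, 1)), pi2, b2, sig),
               expected, tolerance = 1e-10)
  expect_error(gbtm_loglik(Y, trajectory_spec(c(1, 1)), c(1, 0), b2, sig),
               "positive")
})

test_that("posteriors are normalized and follow the priors under equal likelihoods", {
  Y <- matrix(c(0.5, 0.5), nrow = 1)
  spec <- trajectory_spec(c(1, 1))
  b <- list(c(0.5, 0), c(0.5, 0))
  expect_equal(drop(gbtm_posteriors(Y, spec, c(0.5, 0.5), b, 0.1)),
               c(0.5, 0.5))
  expect_equal(drop(gbtm_posteriors(Y, spec, c(0.9, 0.1), b, 0.1)),
               c(0.9, 0.1))
  set.seed(404)
  Yr <- matrix(runif(40), 20, 2)
  b2 <- list(c(0.2, 0.1), c(0.7, 0.1))
  post <- gbtm_posteriors(Yr, spec, c(0.3, 0.7), b2, 0.1)
  expect_equal(rowSums(post), rep(1, 20), tolerance = 1e-10)
  expect_true(all(post >= 0 & post <= 1))
})

test_that("BIC follows the trajectory-macro convention and parameter census", {
  expect_equal(gbtm_bic(-100, 5, 100), -100 - 2.5 * log(100))
  expect_equal(gbtm_bic(-100, 5, 100), -111.5129, tolerance = 1e-4)
  expect_gt(gbtm_bic(-90, 5, 100), gbtm_bic(-100, 5, 100))
  expect_equal(gbtm_n_params(trajectory_spec(c(2, 3, 3, 3))), 19L)
  expect_equal(gbtm_n_params(trajectory_spec(1)), 3L)
})

test_that("AvePP is the mean assigned posterior, bounded below by 1/K", {
  post <- rbind(c(1, 0), c(0.8, 0.2), c(0.6, 0.4), c(0.1, 0.9))
  asg <- max.col(post, ties.method = "first")
  expect_equal(avepp(post, asg), c(0.8, 0.9))
  one_hot <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(avepp(one_hot, max.col(one_hot, ties.method = "first")),
               c(1, 1, 1))
  set.seed(405)
  p <- matrix(runif(60), 30, 2)
  p <- p / rowSums(p)
  a <- max.col(p, ties.method = "first")
  expect_true(all(avepp(p, a) >= 0.5, na.rm = TRUE))
  # empty group reported as NA
  expect_true(is.na(avepp(rbind(c(0.9, 0.1)), 1L)[2]))
})

test_that("EM ascends the log-likelihood and K=1 matches polynomial least squares", {
  cfg <- sim_config(n_patients = 150, pi_true = 1,
                    beta_true = list(c(0.5, 0.2, -0.15)), sigma_true = 0.05,
                    missing_year_rate = 0, seed = 21)
  p <- simulate_coci_panel(cfg)
  stopifnot(all(p$Y > 0 & p$Y < 1))  # fully interior: censoring inert
  fit <- fit_gbtm(p$Y, trajectory_spec(2), n_starts = 3, seed = 2)
  expect_true(all(diff(fit$trace) > -1e-8))
  # ordinary polynomial least squares oracle on the pooled cells
  X <- do.call(rbind, lapply(0:5, function(t) design_row(t, 2, 6)))
  Xl <- X[rep(1:6, each = nrow(p$Y)), ]
  yl <- as.vector(p$Y)
  beta_ls <- drop(solve(crossprod(Xl), crossprod(Xl, yl)))
  expect_equal(unname(fit$beta[[1]]), beta_ls, tolerance = 1e-6)
})

test_that("parameters are recovered on simulated panels", {
  cfg <- separated3_config(500, seed = 31)
  p <- simulate_coci_panel(cfg)
  fit <- fit_gbtm(p$Y, trajectory_spec(c(1, 1, 1)), n_starts = 5, seed = 3)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$pi - cfg$pi_true)), 0.03)
  expect_lt(max(abs(unlist(fit$beta) - unlist(cfg$beta_true))), 0.05)
  expect_lt(abs(fit$sigma - cfg$sigma_true) / cfg$sigma_true, 0.10)
  expect_gt(mean(fit$assignment == p$labels), 0.99)
  expect_equal(sum(fit$group_shares), 1, tolerance = 1e-12)
  expect_equal(rowSums(fit$posteriors), rep(1, fit$n), tolerance = 1e-10)
})

test_that("group labels are stable under permuted initialization", {
  cfg <- separated3_config(200, seed = 41)
  p <- simulate_coci_panel(cfg)
  base_init <- list(pi = c(0.3, 0.3, 0.4),
                    beta = list(c(0.1, 0.1), c(0.5, 0.1), c(0.8, 0.05)),
                    sigma = 0.1)
  f1 <- fit_gbtm(p$Y, trajectory_spec(c(1, 1, 1)), init = base_init)
  perm <- list(pi = base_init$pi[c(3, 1, 2)],
               beta = base_init$beta[c(3, 1, 2)], sigma = 0.1)
  f2 <- fit_gbtm(p$Y, trajectory_spec(c(1, 1, 1)), init = perm)
  expect_equal(f1$pi, f2$pi, tolerance = 1e-6)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-5)
  expect_equal(f1$assignment, f2$assignment)
})

test_that("missing years do not contribute to the likelihood", {
  cfg <- separated3_config(60, seed = 51)
  p <- simulate_coci_panel(cfg)
  Y <- p$Y
  i <- which(rowSums(is.na(Y)) > 0)[1]
  skip_if(is.na(i))
  spec <- trajectory_spec(c(1, 1, 1))
  pi3 <- c(0.4, 0.35, 0.25)
  b3 <- list(c(0.15, 0.1), c(0.45, 0.15), c(0.8, 0.05))
  sig <- 0.08
  # the patient's likelihood term, built by hand over observed years only
  obs <- which(!is.na(Y[i, ]))
  terms <- vapply(1:3, function(g) {
    mu <- vapply(obs - 1L, function(t) sum(design_row(t, 1, 6) * b3[[g]]),
                 numeric(1))
    pi3[g] * prod(exp(cnorm_logdensity(Y[i, obs], mu, sig)))
  }, numeric(1))
  lli <- gbtm_loglik(Y[i, , drop = FALSE], spec, pi3, b3, sig)
  expect_equal(lli, log(sum(terms)), tolerance = 1e-10)
  # and the cohort likelihood decomposes over patients
  ll_rest <- gbtm_loglik(Y[-i, , drop = FALSE], spec, pi3, b3, sig)
  expect_equal(gbtm_loglik(Y, spec, pi3, b3, sig), lli + ll_rest,
               tolerance = 1e-8)
})
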