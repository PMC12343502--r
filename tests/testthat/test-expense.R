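test_that("growth rates reproduce published arithmetic and the identity case", {
  means <- c(2910.89, 3430.88, 3799.14, 4515.39, 4261.27, 4465.40)
  expect_equal(growth_rates(means),
               c(NA, 17.86, 10.73, 18.85, -5.63, 4.79))
  expect_equal(growth_rates(c(100, 100, 100)), c(NA, 0, 0))
  # growth_rate(a, a*(1+g)) returns 100 g up to rounding
  set.seed(601)
  for (i in 1:20) {
    a <- runif(1, 100, 10000); g <- runif(1, -0.5, 0.5)
    expect_equal(growth_rates(c(a, a * (1 + g)))[2], round_half_up(100 * g, 2),
                 tolerance = 5e-3)
  }
})

test_that("group proportions are percentages rounded half-up and sum to ~100", {
  asg <- rep(1:4, c(15901, 5235, 5784, 3625))
  expect_equal(unname(group_proportions(asg)),
               c(52.06, 17.14, 18.94, 11.87))
  expect_equal(unname(group_proportions(rep(1, 10))), 100.00)
  expect_equal(unname(group_proportions(c(1, 2))), c(50.00, 50.00))
  set.seed(602)
  for (i in 1:20) {
    a <- sample(1:5, 500, replace = TRUE)
    expect_lt(abs(sum(group_proportions(a)) - 100), 0.021)
  }
})

test_that("per-capita and per-group expense tables average over all patients", {
  sim <- simulate_claims(sim_config(n_patients = 80, seed = 71))
  panels <- build_panels(read_claims_from_sim(sim), sim$demographics, 2016, 6)
  t1 <- per_capita_series(panels)
  expect_equal(nrow(t1), 6L)
  # oracle: direct mean over the generator's truth totals
  truth <- sim$truth_years[sim$truth_years$patient_id %in%
                             panels$patients$patient_id, ]
  oracle <- tapply(truth$expense_total, truth$year, mean)
  expect_equal(t1$mean_expense, as.numeric(oracle), tolerance = 1e-9)

  asg <- tibble::tibble(patient_id = sim$truth$patient_id,
                        group = sim$truth$label)
  t4 <- group_annual_means(panels, asg)
  # permuting patient order leaves the table unchanged
  asg2 <- asg[sample(nrow(asg)), ]
  expect_equal(group_annual_means(panels, asg2), t4)
  # constant expenses give constant cells
  p2 <- panels
  p2$years$expense_total <- 42
  t4c <- group_annual_means(p2, asg)
  expect_true(all(abs(t4c$mean_expense - 42) < 1e-12, na.rm = TRUE))
})

test_that("the expense design has the documented dummy layout", {
  sim <- simulate_claims(sim_config(n_patients = 60, seed = 81))
  panels <- build_panels(read_claims_from_sim(sim), sim$demographics, 2016, 6)
  panels <- add_upcci(panels)
  asg <- tibble::tibble(patient_id = sim$truth$patient_id,
                        group = sim$truth$label)
  d <- build_design(panels, asg)
  expect_equal(colnames(d$X),
               c("(Intercept)", "G1", "G2", "G3", "male", "age19-59",
                 "age60-74", "employee", "upcci"))
  expect_equal(ncol(d$X), 9L)
  # reference patient: G4, female, 75+, resident, CCI 0 -> intercept only
  ref <- d$data$group == 4 & d$data$male == 0 &
    d$data$age_grp == "75+" & d$data$employee == 0 & d$data$upcci == 0
  if (any(ref)) {
    expect_equal(unname(d$X[which(ref)[1], -1]), rep(0, 8))
  }
  # response is the mean annual total over the horizon
  pid <- d$data$patient_id[1]
  tot <- sum(panels$years$expense_total[panels$years$patient_id == pid])
  expect_equal(d$y[1], tot / 6)
})

test_that("OLS matches the normal-equations oracle and flags rank deficiency", {
  # 6-point fixture, solved independently via the normal equations
  X <- cbind(1, c(0, 1, 2, 3, 4, 5), c(1, 0, 1, 0, 1, 0))
  colnames(X) <- c("(Intercept)", "x", "z")
  y <- c(1.2, 2.7, 4.1, 5.9, 8.2, 9.8)
  beta_oracle <- drop(solve(t(X) %*% X, t(X) %*% y))
  fit <- ols_fit(y, X)
  expect_equal(unname(fit$coefficients$estimate), unname(beta_oracle),
               tolerance = 1e-8)
  resid <- y - drop(X %*% fit$coefficients$estimate)
  expect_lt(max(abs(t(X) %*% resid)) / max(abs(y)), 1e-6)
  # classical SE oracle
  s2 <- sum(resid^2) / (6 - 3)
  se_oracle <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(unname(fit$coefficients$se), unname(se_oracle),
               tolerance = 1e-8)
  expect_equal(fit$coefficients$ci_hi - fit$coefficients$estimate,
               stats::qt(0.975, 3) * fit$coefficients$se, tolerance = 1e-10)
  # noiseless line
  X2 <- cbind(1, 0:5); colnames(X2) <- c("(Intercept)", "x")
  f2 <- suppressWarnings(ols_fit(2 + 3 * (0:5), X2))  # exact fit warns in summary()
  expect_equal(unname(f2$coefficients$estimate), c(2, 3), tolerance = 1e-10)
  expect_equal(f2$r_squared, 1)
  # collinear column named in the error
  X3 <- cbind(X2, dup = X2[, 2])
  expect_error(ols_fit(y, X3), "dup")
})

test_that("the regression recovers generator expense effects", {
  sim <- simulate_claims(sim_config(n_patients = 1500, seed = 91))
  panels <- build_panels(read_claims_from_sim(sim), sim$demographics, 2016, 6)
  panels <- cohort_filter(panels)
  panels <- add_upcci(panels)
  asg <- tibble::tibble(patient_id = sim$truth$patient_id,
                        group = sim$truth$label)
  fit <- expense_regression(panels, asg)
  cf <- fit$coefficients
  g1 <- cf[cf$term == "G1", ]
  true_gap <- 7300 - 4300
  expect_lt(abs(g1$estimate - true_gap), 2 * g1$se)
  emp <- cf[cf$term == "employee", ]
  expect_lt(abs(emp$estimate - 3500), 3 * emp$se)
})
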