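# shared fixtures and independent oracles

# pair-concordance oracle for the continuity index: probability that two
# distinct visits (ordered pairs) share a provider, by exhaustive enumeration
coci_pair_oracle <- function(tally) {
  visits <- rep(seq_along(tally), tally)
  N <- length(visits)
  same <- 0L
  for (a in seq_len(N)) {
    for (b in seq_len(N)) {
      if (a != b && visits[a] == visits[b]) same <- same + 1L
    }
  }
  same / (N * (N - 1))
}

random_tally <- function(max_n = 30L) {
  N <- sample(3:max_n, 1L)
  p <- sample(1:min(N, 6L), 1L)
  tab <- tabulate(sample.int(p, N, replace = TRUE), nbins = p)
  tab[tab > 0]
}

# write a small claims CSV and return its path
write_claims_fixture <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "claims.csv")
  writeLines(lines, path)
  path
}

claims_header <- "patient_id,visit_date,provider_id,primary_dx,expense,insurance_type"

# Reconstruction of the published five-candidate comparison ledger
# (2 to 6 groups; BIC, assigned shares in %, AvePP per group)
published_candidates <- function() {
  list(
    candidate_result(c(2, 3), -35676.64,
                     c(67.73, 32.27), c(0.94, 0.90)),
    candidate_result(c(2, 3, 3), -32433.48,
                     c(50.39, 36.67, 12.94), c(0.91, 0.93, 0.68)),
    candidate_result(c(2, 3, 3, 3), -29415.80,
                     c(52.06, 17.14, 18.94, 11.87), c(0.92, 0.80, 0.80, 0.88)),
    candidate_result(c(2, 3, 3, 3, 3), -28407.92,
                     c(49.90, 4.61, 16.83, 13.93, 14.73),
                     c(0.91, 0.59, 0.82, 0.80, 0.85)),
    candidate_result(c(3, 3, 3, 3, 3, 2), -27700.30,
                     c(47.12, 16.15, 3.27, 14.23, 7.55, 11.67),
                     c(0.90, 0.80, 0.64, 0.87, 0.61, 0.83)))
}

# simulated claims are already one row per visit with normalized codes, so
# they can stand in for the output of read_claims() directly
read_claims_from_sim <- function(sim) sim$claims

# well-separated 3-group linear configuration used in recovery checks
separated3_config <- function(n, seed, pi = c(0.4, 0.35, 0.25)) {
  sim_config(n_patients = n, pi_true = pi,
             beta_true = list(c(0.15, 0.10), c(0.45, 0.15), c(0.80, 0.05)),
             sigma_true = 0.08, missing_year_rate = 0.1, seed = seed)
}
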