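#' Enumerate candidate trajectory specifications
#'
#' For each K in `k_range`, the full Cartesian product of per-group polynomial
#' orders drawn from `order_set` (ordered tuples, so K = 4 with orders
#' \{1,2,3\} yields 3^4 = 81 candidates).
#'
#' @param k_range integer vector of group counts (subset of 1..6).
#' @param order_set polynomial orders to combine (default 1:3).
#' @return list of [trajectory_spec()] objects.
#' @export
enumerate_specs <- function(k_range, order_set = 1:3) {
  if (any(!k_range %in% 1:6)) stop("k_range must lie in 1..6")
  specs <- list()
  for (k in sort(unique(as.integer(k_range)))) {
    grid <- do.call(expand.grid, rep(list(sort(order_set)), k))
    # expand.grid varies the first column fastest; flip for lexicographic order
    grid <- grid[, rev(seq_len(k)), drop = FALSE]
    grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
    specs <- c(specs, lapply(seq_len(nrow(grid)), function(i) {
      trajectory_spec(as.integer(grid[i, ]))
    }))
  }
  specs
}

#' Candidate ledger entry
#'
#' One row of the model-comparison ledger: a spec with its BIC, assigned
#' group shares and AvePP, and the two pass flags used for selection. Can be
#' built from a fit ([as_candidate()]) or directly from reported diagnostics,
#' e.g. to reconstruct a published comparison table.
#'
#' @param orders per-group polynomial orders.
#' @param bic BIC value (trajectory-macro convention, negative).
#' @param shares assigned group shares (proportions in \[0,1\] or percentages;
#'   percentages are detected by values > 1 and rescaled).
#' @param avepp per-group average posterior probabilities.
#' @param converged did the fit converge (default `TRUE`).
#' @param min_share,min_avepp thresholds for the pass flags.
#' @return a `candidate_result` object.
#' @export
candidate_result <- function(orders, bic, shares, avepp, converged = TRUE,
                             min_share = 0.05, min_avepp = 0.7) {
  spec <- trajectory_spec(orders)
  if (length(shares) != spec$k || length(avepp) != spec$k) {
    stop("shares and avepp must have one entry per group")
  }
  if (any(shares > 1)) shares <- shares / 100
  structure(list(
    spec = spec, bic = bic, shares = shares, avepp = avepp,
    converged = isTRUE(converged),
    pass_share = all(shares >= min_share),
    pass_avepp = all(avepp > min_avepp)),
    class = "candidate_result")
}

#' Candidate from a fitted model
#' @param fit a `gbtm_fit`.
#' @inheritParams candidate_result
#' @return a `candidate_result`.
#' @export
as_candidate <- function(fit, min_share = 0.05, min_avepp = 0.7) {
  candidate_result(fit$spec$orders, fit$bic, fit$group_shares,
                   fit$avepp, fit$converged,
                   min_share = min_share, min_avepp = min_avepp)
}

#' Fit every candidate specification
#'
#' Runs [fit_gbtm()] over a list of specs with per-candidate derived seeds,
#' so the grid is reproducible and insensitive to ordering. Individual fit
#' failures are recorded as non-converged candidates, not raised.
#'
#' @param Y COCI matrix or `coc_panels`.
#' @param specs list of [trajectory_spec()] (e.g. from [enumerate_specs()]).
#' @param n_starts,seed,tol,max_iter passed to [fit_gbtm()].
#' @param min_share,min_avepp selection thresholds recorded on candidates.
#' @param keep_fits keep the full `gbtm_fit` objects (memory-heavy for large
#'   grids; default `FALSE`).
#' @return a `gbtm_grid` object: list with `candidates` (list of
#'   `candidate_result`) and, if requested, `fits`.
#' @export
run_grid <- function(Y, specs, n_starts = 20L, seed = 1L, tol = 1e-6,
                     max_iter = 500L, min_share = 0.05, min_avepp = 0.7,
                     keep_fits = FALSE) {
  if (inherits(Y, "coc_panels")) Y <- coci_matrix(Y)
  candidates <- vector("list", length(specs))
  fits <- if (keep_fits) vector("list", length(specs)) else NULL
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    fit <- tryCatch(
      fit_gbtm(Y, spec, n_starts = n_starts,
               seed = derive_seed(seed, i), tol = tol, max_iter = max_iter),
      error = function(e) NULL)
    if (is.null(fit)) {
      candidates[[i]] <- structure(list(
        spec = spec, bic = NA_real_, shares = rep(NA_real_, spec$k),
        avepp = rep(NA_real_, spec$k), converged = FALSE,
        pass_share = FALSE, pass_avepp = FALSE),
        class = "candidate_result")
    } else {
      candidates[[i]] <- as_candidate(fit, min_share, min_avepp)
      if (keep_fits) fits[[i]] <- fit
    }
  }
  structure(list(candidates = candidates, fits = fits,
                 min_share = min_share, min_avepp = min_avepp, seed = seed),
            class = "gbtm_grid")
}

#' Select the best-fitting trajectory model
#'
#' Applies the selection rules: among converged candidates whose assigned
#' group shares are all at least `min_share` and whose AvePP are all above
#' `min_avepp`, pick the one with maximal BIC (closest to 0). Ties go to the
#' smaller K, then to lexicographically smaller orders. Trajectory-shape
#' plausibility (the remaining, qualitative criterion) is left to the
#' analyst, via the ledger and trajectory plot.
#'
#' @param candidates a `gbtm_grid` or list of `candidate_result`s.
#' @param min_share minimum assigned share per group (default 0.05).
#' @param min_avepp minimum AvePP per group (default 0.7).
#' @return a `selection_result`: list with `ledger` (tibble), `chosen` (the
#'   winning `candidate_result`, or `NULL` when nothing passes), and the
#'   thresholds.
#' @export
select_best <- function(candidates, min_share = 0.05, min_avepp = 0.7) {
  if (inherits(candidates, "gbtm_grid")) candidates <- candidates$candidates
  if (length(candidates) == 0L) stop("no candidates supplied")
  ledger <- selection_ledger(candidates, min_share, min_avepp)
  eligible <- which(ledger$converged & ledger$pass_share & ledger$pass_avepp)
  chosen <- NULL
  if (length(eligible)) {
    el <- ledger[eligible, ]
    best_bic <- max(el$bic)
    tied <- eligible[el$bic == best_bic]
    if (length(tied) > 1L) {
      ks <- ledger$k[tied]
      tied <- tied[ks == min(ks)]
      if (length(tied) > 1L) {
        ostr <- vapply(candidates[tied],
                       function(cc) paste(cc$spec$orders, collapse = ","),
                       character(1))
        tied <- tied[order(ostr)][1L]
      }
    }
    chosen <- candidates[[tied[1L]]]
    ledger$chosen <- seq_len(nrow(ledger)) == tied[1L]
  } else {
    ledger$chosen <- FALSE
  }
  structure(list(ledger = ledger, chosen = chosen,
                 min_share = min_share, min_avepp = min_avepp),
            class = "selection_result")
}

# tidy ledger of candidates, with pass flags recomputed from the thresholds
selection_ledger <- function(candidates, min_share, min_avepp) {
  tibble::tibble(
    k = vapply(candidates, function(cc) cc$spec$k, integer(1)),
    orders = vapply(candidates,
                    function(cc) paste(cc$spec$orders, collapse = ","),
                    character(1)),
    bic = vapply(candidates, function(cc) cc$bic, numeric(1)),
    shares_pct = vapply(candidates, function(cc)
      paste(sprintf("%.2f", 100 * cc$shares), collapse = ";"), character(1)),
    avepp = vapply(candidates, function(cc)
      paste(sprintf("%.2f", cc$avepp), collapse = ";"), character(1)),
    converged = vapply(candidates, function(cc) cc$converged, logical(1)),
    pass_share = vapply(candidates, function(cc)
      all(!is.na(cc$shares)) && all(cc$shares >= min_share), logical(1)),
    pass_avepp = vapply(candidates, function(cc)
      all(!is.na(cc$avepp)) && all(cc$avepp > min_avepp), logical(1)))
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Trajectory model selection (min share ", x$min_share,
      ", min AvePP ", x$min_avepp, ")\n", sep = "")
  print(as.data.frame(x$ledger), row.names = FALSE)
  if (is.null(x$chosen)) {
    cat("No candidate satisfies the constraints.\n")
  } else {
    cat("Chosen: ", format(x$chosen$spec),
        ", BIC ", format(x$chosen$bic, digits = 8), "\n", sep = "")
  }
  invisible(x)
}
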