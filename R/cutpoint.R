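# Cross-validated optimal-dichotomization search: candidate thresholds,
# repeated stratified twofold CV with per-fold likelihood-ratio tests,
# logit-method p-value combination, minimum-combined-p selection and the
# 10/500 training-set stability filter.

#' Candidate dichotomization thresholds
#'
#' Midpoints between consecutive distinct sorted values, restricted so
#' that each side of every candidate holds at least `min_group`
#' observations (avoiding degenerate 2x2 fits in small subsets).
#'
#' @param values numeric vector (non-finite entries dropped).
#' @param min_group minimum group size on each side (default 5).
#' @return sorted numeric vector of candidate cutpoints.
#' @export
candidate_cutpoints <- function(values, min_group = 5) {
  v <- sort(values[is.finite(values)])
  n <- length(v)
  if (n < 2 * min_group)
    stop("need at least ", 2 * min_group, " finite values, got ", n)
  lo <- v[-n]
  hi <- v[-1L]
  mid <- (lo + hi) / 2
  distinct <- hi > lo
  # i values are <= v[i]; each side must hold >= min_group observations
  i <- seq_len(n - 1L)
  ok <- distinct & i >= min_group & (n - i) >= min_group
  cand <- unique(mid[ok])
  if (length(cand) == 0L)
    stop("no candidate leaves ", min_group, " observations on both sides")
  cand
}

#' Combine p-values by the logit method
#'
#' Mudholkar-George combination: with `k` p-values, the statistic
#' `T = -sum(logit(p_i)) * sqrt(3 * (5k + 4) / (k * pi^2 * (5k + 2)))`
#' is referred to the upper tail of a t distribution with `5k + 4`
#' degrees of freedom. p-values at 0 or 1 are clipped to
#' `[1e-15, 1 - 1e-15]` with a warning.
#'
#' @param ps numeric vector of p-values in (0, 1), length >= 1.
#' @return the combined p-value.
#' @export
combine_pvalues_logit <- function(ps) {
  ps <- ps[!is.na(ps)]
  k <- length(ps)
  if (k == 0L) stop("no p-values to combine")
  if (any(ps < 0 | ps > 1)) stop("p-values must lie in [0, 1]")
  if (any(ps <= 0 | ps >= 1)) {
    warning("p-values at 0 or 1 clipped to [1e-15, 1 - 1e-15]")
    ps <- pmin(pmax(ps, 1e-15), 1 - 1e-15)
  }
  const <- sqrt(3 * (5 * k + 4) / (k * pi^2 * (5 * k + 2)))
  T <- -sum(log(ps / (1 - ps))) * const
  stats::pt(T, df = 5 * k + 4, lower.tail = FALSE)
}

#' Dichotomize a continuous vector at a cutpoint
#'
#' @param values numeric vector.
#' @param cutpoint finite threshold; high class is `value > cutpoint`.
#' @return integer 0/1 vector; missing values stay missing.
#' @export
dichotomize <- function(values, cutpoint) {
  if (!is.finite(cutpoint)) stop("cutpoint must be finite")
  as.integer(values > cutpoint)
}

# Per-fold likelihood-ratio p-values of pCR ~ 1{x > c}, vectorized over all
# candidates via the closed-form 2x2 binomial MLE (identical to fitting the
# one-predictor logistic model and G-testing it against intercept-only).
fold_lr_pvalues <- function(x, y, candidates) {
  o <- order(x)
  sx <- x[o]
  cum_e <- cumsum(y[o])
  nf <- length(x)
  Ef <- cum_e[nf]
  if (Ef == 0L || Ef == nf)
    return(rep(NA_real_, length(candidates)))
  n_lo <- findInterval(candidates, sx)    # count of x <= c
  n_hi <- nf - n_lo
  e_lo <- ifelse(n_lo == 0L, 0, cum_e[pmax(n_lo, 1L)])
  e_hi <- Ef - e_lo
  ll_full <- xlogy(e_lo, e_lo / n_lo) + xlogy(n_lo - e_lo, 1 - e_lo / n_lo) +
    xlogy(e_hi, e_hi / n_hi) + xlogy(n_hi - e_hi, 1 - e_hi / n_hi)
  ll_null <- xlogy(Ef, Ef / nf) + xlogy(nf - Ef, 1 - Ef / nf)
  stat <- pmax(0, 2 * (ll_full - ll_null))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p[n_lo == 0L | n_hi == 0L] <- NA_real_  # empty group: fold skipped
  p
}

#' Cross-validated cutpoint search with combined p-values
#'
#' Repeats twofold cross-validation `n_repeats` times with folds
#' stratified (balanced) on the pCR outcome. In every repeat each fold is
#' dichotomized at every candidate threshold and the df = 1
#' likelihood-ratio p-value of `pCR ~ 1{biomarker > c}` is recorded; both
#' folds contribute their p in the test role (2 x `n_repeats` test
#' p-values per candidate), and the candidate minimizing the first fold's
#' p-curve — the training role — earns one selection count per repeat.
#' Test p-values are combined per candidate with
#' [combine_pvalues_logit()]; folds where a candidate empties a group are
#' skipped for that candidate (recorded in `n_skipped`), not imputed.
#'
#' The cutpoint with the minimum combined test p is selected, subject to a
#' stability filter. Two readings of the filter are available:
#' \describe{
#'   \item{selected (default)}{the minimum-combined-p candidate must itself
#'     have been the training argmin in at least `stability_min` of the
#'     repeats, else no cutpoint is returned;}
#'   \item{prefilter}{candidates are first restricted to those with
#'     training count >= `stability_min`, and the combined-p minimum is
#'     taken among them.}
#' }
#' Ties in combined p go to the smaller cutpoint.
#'
#' @param biomarker numeric vector (missing values excluded pairwise).
#' @param pcr binary 0/1 outcome aligned with `biomarker`.
#' @param n_repeats number of CV repeats (default 500).
#' @param folds folds per repeat; only 2 is supported.
#' @param stability_min minimum training selections (default 10).
#' @param min_group candidate-grid group minimum, see
#'   [candidate_cutpoints()].
#' @param stability_rule `"selected"` or `"prefilter"` (see above).
#' @param seed integer RNG seed.
#' @param endpoint optional endpoint id carried into the result.
#' @return a `cutpoint_result`: `candidates`, `combined_p_test`,
#'   `train_select_count`, `n_test_p`, `n_skipped`, `selected`,
#'   `selected_index`, `pass_stability`, `argmin_test`, plus the run
#'   parameters.
#' @export
cv_cutpoint_search <- function(biomarker, pcr, n_repeats = 500, folds = 2,
                               stability_min = 10, min_group = 5,
                               stability_rule = c("selected", "prefilter"),
                               seed = 1, endpoint = NULL) {
  stability_rule <- match.arg(stability_rule)
  if (folds != 2L) stop("only twofold cross-validation is supported")
  keep <- !is.na(biomarker) & !is.na(pcr)
  x <- biomarker[keep]
  y <- as.integer(pcr[keep])
  if (sum(y) < 3L || sum(1 - y) < 3L)
    stop("need at least 3 events and 3 non-events")
  cand <- candidate_cutpoints(x, min_group = min_group)
  K <- length(cand)

  ev <- which(y == 1L)
  nev <- which(y == 0L)
  sum_logit <- numeric(K)
  n_test <- integer(K)
  n_skip <- integer(K)
  counts <- integer(K)

  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      f1 <- c(ev[sample.int(length(ev), length(ev) %/% 2L)],
              nev[sample.int(length(nev), length(nev) %/% 2L)])
      in1 <- logical(length(y))
      in1[f1] <- TRUE
      p1 <- fold_lr_pvalues(x[in1], y[in1], cand)
      p2 <- fold_lr_pvalues(x[!in1], y[!in1], cand)
      for (p in list(p1, p2)) {
        ok <- !is.na(p)
        pc <- pmin(pmax(p[ok], 1e-15), 1 - 1e-15)
        sum_logit[ok] <- sum_logit[ok] + log(pc / (1 - pc))
        n_test[ok] <- n_test[ok] + 1L
        n_skip[!ok] <- n_skip[!ok] + 1L
      }
      # fold 1 in its training role: its argmin earns the repeat's count
      if (any(!is.na(p1))) {
        arg <- which.min(p1)  # ties -> first = smallest cutpoint
        counts[arg] <- counts[arg] + 1L
      }
    }
  })

  # combined p kept on the log scale: under strong signal the t tail
  # underflows to 0 in double precision and the argmin would otherwise
  # degenerate to a tie-break among underflowed candidates
  log_combined <- rep(NA_real_, K)
  for (j in seq_len(K)) {
    if (n_test[j] == 0L) next
    k <- n_test[j]
    const <- sqrt(3 * (5 * k + 4) / (k * pi^2 * (5 * k + 2)))
    log_combined[j] <- stats::pt(-sum_logit[j] * const, df = 5 * k + 4,
                                 lower.tail = FALSE, log.p = TRUE)
  }
  combined <- exp(log_combined)

  argmin_test <- if (all(is.na(log_combined))) NA_integer_ else
    which.min(log_combined)
  if (stability_rule == "selected") {
    pass <- !is.na(argmin_test) && counts[argmin_test] >= stability_min
    sel_idx <- if (pass) argmin_test else NA_integer_
  } else {
    eligible <- which(counts >= stability_min & !is.na(log_combined))
    pass <- length(eligible) > 0L
    sel_idx <- if (pass) eligible[which.min(log_combined[eligible])] else
      NA_integer_
  }

  structure(list(endpoint = endpoint, candidates = cand,
                 combined_p_test = combined,
                 combined_logp_test = log_combined,
                 train_select_count = counts,
                 n_test_p = n_test, n_skipped = n_skip,
                 selected = if (!is.na(sel_idx)) cand[sel_idx] else
                   NA_real_,
                 selected_index = sel_idx, argmin_test = argmin_test,
                 pass_stability = pass, n_repeats = n_repeats,
                 stability_min = stability_min,
                 stability_rule = stability_rule, min_group = min_group,
                 seed = seed, n = length(y), n_events = sum(y)),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("cutpoint_result%s: %d candidates, %d repeats\n",
              if (!is.null(x$endpoint)) paste0(" [", x$endpoint, "]") else "",
              length(x$candidates), x$n_repeats))
  if (x$pass_stability)
    cat(sprintf("  selected %.6g (combined p = %.3g, training count %d/%d)\n",
                x$selected, x$combined_p_test[x$selected_index],
                x$train_select_count[x$selected_index], x$n_repeats))
  else
    cat("  no stable cutpoint (stability filter failed)\n")
  invisible(x)
}
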