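# Maximum-likelihood logistic fits, likelihood-ratio tests, and the four
# pre-specified biomarker screening model forms (arm-wise, interaction,
# receptor-adjusted interaction), per biomarker or matrix-wide.

loglik_bernoulli <- function(y, eta) {
  # numerically stable sum(y*eta - log(1 + exp(eta)))
  sum(y * eta - ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))))
}

newton_logistic <- function(y, X, penalty = 0, tol = 1e-8, maxit = 100L) {
  p <- ncol(X)
  beta <- numeric(p)
  pen_ll <- function(b) loglik_bernoulli(y, drop(X %*% b)) -
    penalty / 2 * sum(b^2)
  ll_old <- pen_ll(beta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(X, y - mu)) - penalty * beta
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X) + diag(penalty, p)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving keeps Newton monotone on near-separated data
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- pen_ll(cand)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    beta <- beta + lam * step
    ll_old <- pen_ll(beta)
  }
  list(beta = stats::setNames(beta, colnames(X)),
       loglik = loglik_bernoulli(y, drop(X %*% beta)),
       converged = converged, iterations = it)
}

#' Fit a logistic regression by Newton-Raphson
#'
#' MLE of a binary-outcome logistic model, iterated to gradient-norm
#' tolerance 1e-8 (at most 100 iterations). Constant and aliased design
#' columns are dropped (and recorded). If the fit fails to converge or any
#' coefficient exceeds 15 on the standardized scale — the signature of
#' (quasi-)separation — the model is refit with a small ridge penalty
#' (`epsilon = 1e-4`) and `separation_flag` is set; downstream screens
#' surface the flag rather than erroring on tiny subsets.
#'
#' @param outcome binary 0/1 vector.
#' @param design numeric matrix with named columns, including the intercept
#'   column if one is wanted.
#' @param penalty ridge penalty on all coefficients (default 0 = plain MLE).
#' @return a `logistic_fit`: coefficients, `log_likelihood` (unpenalized,
#'   at the returned coefficients), `converged`, `separation_flag`, `n`,
#'   `n_events`, `terms`, `dropped`.
#' @export
fit_logistic <- function(outcome, design, penalty = 0) {
  y <- as.numeric(outcome)
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2L) stop("degenerate outcome (all ", y[1L], ")")
  X <- as.matrix(design)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop("design/outcome length mismatch")
  if (anyNA(X)) stop("design contains missing values")

  sds <- apply(X, 2L, stats::sd)
  is_intercept <- apply(X, 2L, function(col) all(col == 1))
  keep <- sds > 0 | is_intercept
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  if (ncol(X) > 0L) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
      dropped <- c(dropped, aliased)
      X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
    }
  }
  if (ncol(X) == 0L) stop("no usable design columns")
  if (nrow(X) < ncol(X) + 1L) stop("fewer observations than parameters + 1")

  fit <- newton_logistic(y, X, penalty = penalty)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0] <- 1
  sep <- !fit$converged || any(abs(fit$beta * scale) > 15)
  separation_flag <- FALSE
  if (sep && penalty == 0) {
    separation_flag <- TRUE
    fit <- newton_logistic(y, X, penalty = 1e-4)
  }
  structure(list(terms = colnames(X), coefficients = fit$beta,
                 log_likelihood = fit$loglik, converged = fit$converged,
                 separation_flag = separation_flag,
                 n = length(y), n_events = sum(y), dropped = dropped,
                 penalty = if (separation_flag) 1e-4 else penalty,
                 outcome = y),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic_fit: n=%d, events=%d, logLik=%.4f%s\n", x$n,
              x$n_events, x$log_likelihood,
              if (x$separation_flag) " [separation: ridge refit]" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Likelihood-ratio test between nested logistic fits
#'
#' Statistic `2 * (llik_full - llik_reduced)` clipped at zero, referred to
#' the upper tail of a chi-square with df = difference in retained term
#' counts. Both fits must be on the same patients (checked against the
#' stored outcome vectors) and the reduced terms must nest in the full
#' terms.
#'
#' @param full,reduced `logistic_fit` objects.
#' @return list `statistic`, `df`, `p`.
#' @export
lr_pvalue <- function(full, reduced) {
  stopifnot(inherits(full, "logistic_fit"), inherits(reduced, "logistic_fit"))
  if (full$n != reduced$n || !identical(full$outcome, reduced$outcome))
    stop("mismatched patient sets between full and reduced fits")
  if (!all(reduced$terms %in% full$terms))
    stop("reduced model terms are not a subset of the full model terms")
  df <- length(full$terms) - length(reduced$terms)
  stat <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  # identical models (df 0) carry no evidence: p = 1 by convention
  p <- if (df == 0L) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

subset_rows <- function(clinical, subset) {
  switch(subset,
         "all" = rep(TRUE, nrow(clinical)),
         "HER2+" = clinical$her2 == 1L,
         "TN" = clinical$hr == 0L & clinical$her2 == 0L,
         "HR+HER2-" = clinical$hr == 1L & clinical$her2 == 0L,
         stop("unknown subset '", subset, "'"))
}

#' Screen one biomarker against pCR under a pre-specified model form
#'
#' The four model forms mirror the pre-specified analysis plan:
#' \describe{
#'   \item{treated_arm / control_arm}{`pCR ~ biomarker` within that arm
#'     (and receptor subset), LR test of the biomarker term;}
#'   \item{interaction}{`pCR ~ treatment + biomarker +
#'     treatment:biomarker` on both arms, LR test of the interaction term;}
#'   \item{interaction_adjusted}{the interaction model with HR and HER2
#'     main effects added.}
#' }
#' All tests are df = 1 likelihood-ratio tests; p-values are descriptive
#' (no multiplicity correction at this stage). Patients missing the
#' biomarker are excluded from this biomarker's models only. Subsets with
#' fewer than 10 patients or fewer than 3 events are flagged
#' `"underpowered"` but still reported; constant biomarkers and degenerate
#' outcomes yield a flagged null row rather than an error.
#'
#' @param biomarker numeric vector aligned with `clinical` rows.
#' @param clinical a `clinical_table`.
#' @param population one of `"treated_arm"`, `"control_arm"`,
#'   `"interaction"`, `"interaction_adjusted"`.
#' @param subset one of `"all"`, `"HER2+"`, `"TN"`, `"HR+HER2-"`.
#' @param id biomarker id for the output row.
#' @return one-row data.frame: `biomarker`, `population`, `subset`,
#'   `direction` (sign of the tested coefficient), `lr_p`, `n`, `n_pcr`,
#'   `flags`.
#' @export
screen <- function(biomarker, clinical,
                   population = c("treated_arm", "control_arm",
                                  "interaction", "interaction_adjusted"),
                   subset = c("all", "HER2+", "TN", "HR+HER2-"),
                   id = "biomarker") {
  population <- match.arg(population)
  subset <- match.arg(subset)
  stopifnot(length(biomarker) == nrow(clinical))

  rows <- subset_rows(clinical, subset) & !is.na(biomarker)
  if (population == "treated_arm") rows <- rows & clinical$arm == "treated"
  if (population == "control_arm") rows <- rows & clinical$arm == "control"
  y <- clinical$pcr[rows]
  x <- biomarker[rows]
  trt <- as.integer(clinical$arm[rows] == "treated")
  hr <- clinical$hr[rows]
  her2 <- clinical$her2[rows]

  n <- length(y)
  n_pcr <- sum(y)
  flags <- character(0)
  if (n < 10L || n_pcr < 3L || (n - n_pcr) < 3L)
    flags <- c(flags, "underpowered")

  res <- function(direction, p, flags) data.frame(
    biomarker = id, population = population, subset = subset,
    direction = direction, lr_p = p, n = n, n_pcr = n_pcr,
    flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)

  if (n < 4L || length(unique(y)) < 2L || length(unique(x)) < 2L)
    return(res(0L, NA_real_, c(flags, "degenerate")))

  fitted <- tryCatch({
    if (population %in% c("treated_arm", "control_arm")) {
      Xf <- cbind("(Intercept)" = 1, biomarker = x)
      Xr <- Xf[, 1L, drop = FALSE]
      tested <- "biomarker"
    } else {
      Xf <- cbind("(Intercept)" = 1, treatment = trt, biomarker = x,
                  "treatment:biomarker" = trt * x)
      if (population == "interaction_adjusted")
        Xf <- cbind(Xf, hr = hr, her2 = her2)
      Xr <- Xf[, colnames(Xf) != "treatment:biomarker", drop = FALSE]
      tested <- "treatment:biomarker"
    }
    full <- fit_logistic(y, Xf)
    if (!tested %in% full$terms) stop("tested term aliased")
    reduced <- fit_logistic(y, Xr)
    lr <- lr_pvalue(full, reduced)
    # the tested term is the single added one, so df should be 1
    if (full$separation_flag || reduced$separation_flag)
      flags <- c(flags, "separation")
    list(direction = sign(unname(full$coefficients[tested])), p = lr$p,
         flags = flags)
  }, error = function(e) NULL)

  if (is.null(fitted))
    return(res(0L, NA_real_, c(flags, "degenerate")))
  res(as.integer(fitted$direction), fitted$p, fitted$flags)
}

#' Screen every feature of a matrix against pCR
#'
#' Applies [screen()] to every row of an omics matrix under one model form
#' and reports the count of features with `lr_p < alpha` (descriptive, no
#' multiplicity correction — the downstream enrichment module owns BH).
#'
#' @param matrix an `omics_matrix` whose columns align with `clinical`.
#' @param clinical a `clinical_table`.
#' @inheritParams screen
#' @param alpha descriptive significance threshold (default 0.05).
#' @return list: `table` (one row per feature) and `n_pass`.
#' @export
screen_all <- function(matrix, clinical,
                       population = "treated_arm", subset = "all",
                       alpha = 0.05) {
  stopifnot(inherits(matrix, "omics_matrix"))
  v <- matrix$values[, clinical$patient_id, drop = FALSE]
  rows <- lapply(seq_len(nrow(v)), function(i)
    screen(v[i, ], clinical, population = population, subset = subset,
           id = rownames(v)[i]))
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(biomarker = character(0), population = character(0),
               subset = character(0), direction = integer(0),
               lr_p = numeric(0), n = integer(0), n_pcr = integer(0),
               flags = character(0), stringsAsFactors = FALSE)
  list(table = tab, n_pass = sum(tab$lr_p < alpha, na.rm = TRUE))
}

#' Mean-expression signature score
#'
#' Per-patient unweighted mean of the member genes' rows after per-gene
#' median centering — the "mean expression of genes in the pathway" score
#' used for exploratory pathway summaries.
#'
#' @param expression an `omics_matrix` (log-scale expression).
#' @param gene_set character vector of member gene ids.
#' @return named numeric vector, one score per patient.
#' @export
signature_score <- function(expression, gene_set) {
  stopifnot(inherits(expression, "omics_matrix"))
  present <- intersect(gene_set, rownames(expression$values))
  if (length(present) == 0L)
    stop("no genes of the set are present in the matrix: ",
         fmt_ids(gene_set))
  missing <- setdiff(gene_set, present)
  if (length(missing))
    message("signature_score: ", length(missing), " gene(s) absent (",
            fmt_ids(missing), ")")
  m <- expression$values[present, , drop = FALSE]
  centered <- m - apply(m, 1L, stats::median, na.rm = TRUE)
  colMeans(centered, na.rm = TRUE)
}
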