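# Independent oracles and tiny fixture builders shared across tests.
# These deliberately avoid the package's own code paths.

# Brute-force 2-parameter logistic MLE by iterated grid refinement.
grid_mle2 <- function(y, x, lims = c(-8, 8)) {
  ll <- function(b0, b1) sum(y * (b0 + b1 * x) - log1p(exp(b0 + b1 * x)))
  b0s <- seq(lims[1L], lims[2L], length.out = 81L)
  b1s <- b0s
  for (round in 1:5) {
    grid <- outer(b0s, b1s, Vectorize(ll))
    ij <- arrayInd(which.max(grid), dim(grid))
    c0 <- b0s[ij[1L]]
    c1 <- b1s[ij[2L]]
    h0 <- (b0s[2L] - b0s[1L]) * 4
    h1 <- (b1s[2L] - b1s[1L]) * 4
    b0s <- seq(c0 - h0, c0 + h0, length.out = 81L)
    b1s <- seq(c1 - h1, c1 + h1, length.out = 81L)
  }
  c(b0 = c0, b1 = c1)
}

# G-test (binomial deviance) p-value for a 2x2 exposure-by-outcome table,
# by the direct 2 * sum(O * log(O / E)) formula.
gtest_2x2_p <- function(y, g) {
  O <- as.vector(table(factor(g, levels = 0:1), factor(y, levels = 0:1)))
  E <- outer(tabulate(factor(g, levels = 0:1), 2L),
             tabulate(factor(y, levels = 0:1), 2L)) / length(y)
  G <- 2 * sum(ifelse(O == 0, 0, O * log(O / as.vector(E))))
  pchisq(G, df = 1, lower.tail = FALSE)
}

# Independent arrangement of the logit-method p-value combination.
logit_comb_oracle <- function(p) {
  k <- length(p)
  scale <- sqrt(k * pi^2 * (5 * k + 2) / (3 * (5 * k + 4)))
  pt(-sum(qlogis(p)) / scale, df = 5 * k + 4, lower.tail = FALSE)
}

# Posterior mean of inverse-logit(intercept) for intercept-only data by
# 1-D numeric integration of the exact posterior.
quadrature_rate_oracle <- function(events, n, prior_sd) {
  logpost <- function(b) events * b - n * log1p(exp(b)) +
    dnorm(b, 0, prior_sd, log = TRUE)
  num <- integrate(function(b) plogis(b) * exp(logpost(b)), -40, 40,
                   rel.tol = 1e-10)$value
  den <- integrate(function(b) exp(logpost(b)), -40, 40,
                   rel.tol = 1e-10)$value
  num / den
}

# Minimal in-memory clinical table.
toy_clinical <- function(n = 20, pcr = NULL, arm = NULL, hr = NULL,
                         her2 = NULL, seed = 1) {
  set.seed(seed)
  pcr <- pcr %||% rbinom(n, 1, 0.3)
  arm <- arm %||% rep(c("control", "treated"), length.out = n)
  hr <- hr %||% rbinom(n, 1, 0.5)
  her2 <- her2 %||% rbinom(n, 1, 0.25)
  pcrscreen:::new_clinical_table(sprintf("P%03d", seq_len(n)), arm, hr,
                                 her2, rep("unknown", n), pcr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_fixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
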