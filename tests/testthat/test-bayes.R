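test_that("the 8-term design matrix encodes covariates and products", {
  cl <- toy_clinical(4, arm = c("treated", "control", "treated", "control"),
                     hr = c(1, 0, 0, 1), her2 = c(0, 0, 1, 1),
                     pcr = c(1, 0, 1, 0))
  X <- build_design(cl, c(1, 0, 0, 1))
  expect_equal(colnames(X),
               c("(Intercept)", "hr", "her2", "biomarker", "treatment",
                 "treatment:hr", "treatment:her2", "treatment:biomarker"))
  expect_equal(unname(X[1, ]), c(1, 1, 0, 1, 1, 1, 0, 1))
  expect_equal(unname(X[2, ]), c(1, 0, 0, 0, 0, 0, 0, 0))

  # full factorial of the four binary inputs spans rank 8
  g <- expand.grid(hr = 0:1, her2 = 0:1, bm = 0:1, trt = 0:1)
  clf <- toy_clinical(16, arm = ifelse(g$trt == 1, "treated", "control"),
                      hr = g$hr, her2 = g$her2,
                      pcr = rep(c(0, 1), 8))
  Xf <- build_design(clf, g$bm)
  expect_equal(qr(Xf)$rank, 8L)

  expect_error(build_design(cl, c(0.3, 0, 1, 1)), "binary")
  expect_silent(build_design(cl, c(0.3, 0, 1, 1), allow_continuous = TRUE))
})

test_that("with no data the posterior reproduces the prior", {
  X <- build_design(toy_clinical(2), c(0, 1))[0, , drop = FALSE]
  post <- sample_posterior(X, numeric(0),
                           bayes_model_spec(chains = 2, iterations = 20000,
                                            burnin = 2000, seed = 2))
  expect_true("prior_dominated" %in% post$flags)
  m <- colMeans(post$draws)
  s <- apply(post$draws, 2, sd)
  expect_lt(max(abs(m)), 0.4)          # prior mean 0, MC error allowance
  expect_lt(max(abs(s - 3) / 3), 0.05) # prior sd 3 within 5%
})

test_that("intercept-only posterior matches the quadrature oracle", {
  y <- rep(c(1, 0), c(6, 4))
  X <- matrix(1, 10, 1, dimnames = list(NULL, "(Intercept)"))
  post <- sample_posterior(X, y,
                           bayes_model_spec(prior_sd = 100, chains = 2,
                                            iterations = 8000,
                                            burnin = 2000, seed = 3))
  est <- mean(plogis(post$draws[, 1]))
  expect_lt(abs(est - quadrature_rate_oracle(6, 10, 100)), 0.02)
})

test_that("flat-prior posterior means converge to the MLE at large n", {
  cfg <- sim_config(n_per_arm = 2500,
                    biomarkers = biomarker_spec("bm", effect = "step",
                                                theta = exp(9),
                                                delta = 0.5,
                                                delta_trt = 1.0),
                    seed = 7)
  sim <- generate_cohort(cfg)
  cl <- sim$cohort$clinical
  bmb <- dichotomize(sim$truth$pre_batch_rppa["bm", cl$patient_id], exp(9))
  X <- build_design(cl, bmb)
  mle <- fit_logistic(cl$pcr, X)$coefficients
  post <- sample_posterior(X, cl$pcr,
                           bayes_model_spec(prior_sd = 100, chains = 2,
                                            iterations = 6000,
                                            burnin = 2000, seed = 5))
  expect_lt(max(abs(colMeans(post$draws) - mle)), 0.05)
  expect_true(all(post$rhat < 1.05))
})

test_that("flipping the biomarker coding leaves subset estimates unchanged", {
  cfg <- sim_config(n_per_arm = 200,
                    biomarkers = biomarker_spec("bm", effect = "step",
                                                theta = exp(9), delta = 0.8,
                                                delta_trt = 0.8),
                    seed = 13)
  sim <- generate_cohort(cfg)
  cl <- sim$cohort$clinical
  bmb <- dichotomize(sim$truth$pre_batch_rppa["bm", cl$patient_id], exp(9))
  spec <- bayes_model_spec(chains = 2, iterations = 8000, burnin = 2000,
                           seed = 9)
  Xa <- build_design(cl, bmb)
  Xb <- build_design(cl, 1L - bmb)
  pa <- sample_posterior(Xa, cl$pcr, spec)
  pb <- sample_posterior(Xb, cl$pcr, spec)

  sub <- cl$arm == "treated" & bmb == 1L
  ea <- subset_pcr_estimate(pa, Xa, sub, "bm-high treated")
  eb <- subset_pcr_estimate(pb, Xb, sub, "bm-high treated")
  expect_lt(abs(ea$mean - eb$mean), 0.02)
  # sign structure flips on the biomarker terms
  expect_lt(abs(mean(pa$draws[, "treatment:biomarker"]) +
                mean(pb$draws[, "treatment:biomarker"])), 0.15)
})

test_that("subset estimates are predictive means over the subset rows", {
  cl <- toy_clinical(6, arm = rep("treated", 6), hr = rep(0, 6),
                     her2 = rep(0, 6), pcr = c(1, 0, 1, 0, 1, 0))
  X <- build_design(cl, c(1, 1, 0, 0, 1, 0))
  # degenerate posterior: all draws equal a fixed coefficient vector
  beta <- c(-1, 0, 0, 2, 0.5, 0, 0, 1)
  fake <- structure(list(draws = matrix(rep(beta, each = 50), 50,
                                        dimnames = list(NULL,
                                                        colnames(X)))),
                    class = "posterior_summary")
  sub1 <- c(TRUE, rep(FALSE, 5))
  e1 <- subset_pcr_estimate(fake, X, sub1, "one row")
  expect_equal(unique(e1$draws), plogis(sum(beta * X[1, ])))

  eall <- subset_pcr_estimate(fake, X, rep(TRUE, 6), "all")
  expect_equal(eall$mean, mean(plogis(X %*% beta)))

  expect_error(subset_pcr_estimate(fake, X, rep(FALSE, 6), "nobody"),
               "empty subset: nobody")
})

test_that("zero-event data is flagged but still yields a posterior", {
  cl <- toy_clinical(12, pcr = rep(0L, 12))
  X <- build_design(cl, rep(c(0, 1), 6))
  post <- suppressWarnings(  # small-n designs may also be rank deficient
    sample_posterior(X, cl$pcr,
                     bayes_model_spec(chains = 2, iterations = 3000,
                                      burnin = 1000, seed = 4)))
  expect_true("prior_dominated" %in% post$flags)
  expect_equal(nrow(post$draws), 2 * 2000)
})
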