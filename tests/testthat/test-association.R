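test_that("logistic MLE matches closed forms and the grid-search oracle", {
  # intercept only, 6 events of 10
  y <- rep(c(1, 0), c(6, 4))
  f0 <- fit_logistic(y, cbind("(Intercept)" = rep(1, 10)))
  expect_equal(unname(f0$coefficients), log(6 / 4), tolerance = 1e-7)
  expect_equal(f0$log_likelihood, 6 * log(0.6) + 4 * log(0.4),
               tolerance = 1e-10)

  # 2x2: high 8/10 pCR, low 2/10 -> slope log(16)
  g <- rep(c(1, 0), each = 10)
  y2 <- c(rep(c(1, 0), c(8, 2)), rep(c(1, 0), c(2, 8)))
  f2 <- fit_logistic(y2, cbind("(Intercept)" = 1, x = g))
  expect_equal(unname(f2$coefficients["x"]), log(16), tolerance = 1e-6)
  oracle <- grid_mle2(y2, g)
  expect_lt(max(abs(f2$coefficients - oracle)), 1e-4)

  # random small continuous designs vs grid search
  set.seed(14)
  for (i in 1:5) {
    n <- sample(12:30, 1)
    x <- rnorm(n)
    yy <- rbinom(n, 1, plogis(0.3 + 0.8 * x))
    if (length(unique(yy)) < 2) next
    fit <- fit_logistic(yy, cbind("(Intercept)" = 1, x = x))
    if (fit$separation_flag) next
    expect_lt(max(abs(fit$coefficients - grid_mle2(yy, x))), 1e-4)
  }
})

test_that("likelihood-ratio test agrees with the G-test and handles edge cases", {
  g <- rep(c(1, 0), each = 10)
  y <- c(rep(c(1, 0), c(8, 2)), rep(c(1, 0), c(2, 8)))
  full <- fit_logistic(y, cbind("(Intercept)" = 1, x = g))
  reduced <- fit_logistic(y, cbind("(Intercept)" = rep(1, 20)))
  lr <- lr_pvalue(full, reduced)
  expect_equal(lr$df, 1L)
  expect_equal(lr$p, gtest_2x2_p(y, g), tolerance = 1e-8)

  # full == reduced: statistic 0, p = 1
  same <- lr_pvalue(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  other <- fit_logistic(rev(y), cbind("(Intercept)" = rep(1, 20)))
  expect_error(lr_pvalue(full, other), "mismatched patient sets")
})

test_that("separation is flagged and resolved by the ridge refit", {
  y <- rep(c(0, 1), each = 8)
  x <- c(rnorm(8, -3), rnorm(8, 3))  # perfect separation
  fit <- fit_logistic(y, cbind("(Intercept)" = 1, x = x))
  expect_true(fit$separation_flag)
  expect_true(all(is.finite(fit$coefficients)))
  expect_error(fit_logistic(rep(1, 10), cbind("(Intercept)" = rep(1, 10))),
               "degenerate outcome")
})

test_that("LR p-values are invariant to affine biomarker rescaling", {
  set.seed(22)
  cl <- toy_clinical(80, pcr = rbinom(80, 1, 0.35))
  x <- rlnorm(80, 9, 0.5)
  p1 <- screen(x, cl, "interaction")$lr_p
  p2 <- screen(100 + 0.001 * x, cl, "interaction")$lr_p
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("screen builds the right model per population and flags small cells", {
  set.seed(30)
  cfg <- sim_config(n_per_arm = 200,
                    biomarkers = biomarker_spec("x", beta_bm = 1.2),
                    seed = 44)
  sim <- generate_cohort(cfg)
  cl <- sim$cohort$clinical
  z <- sim$truth$z[cl$patient_id, "x"]

  r_trt <- screen(z, cl, "treated_arm")
  expect_lt(r_trt$lr_p, 0.05)
  expect_equal(r_trt$direction, 1L)
  expect_equal(r_trt$n, sum(cl$arm == "treated"))

  r_sub <- screen(z, cl, "treated_arm", subset = "HER2+")
  expect_lte(r_sub$n, sum(cl$her2 == 1))

  # constant biomarker: flagged null, not an error
  r_const <- screen(rep(2, nrow(cl)), cl, "treated_arm")
  expect_true(grepl("degenerate", r_const$flags))
  expect_true(is.na(r_const$lr_p))
  expect_equal(r_const$direction, 0L)

  # tiny subset: underpowered flag with p still reported
  cl_small <- cl[c(which(cl$arm == "control")[1:9],
                   which(cl$arm == "treated")[1:2]), ]
  r_small <- screen(z[c(which(cl$arm == "control")[1:9],
                        which(cl$arm == "treated")[1:2])],
                    cl_small, "control_arm")
  expect_true(grepl("underpowered", r_small$flags))
})

test_that("arm-wise null p-values are exchangeable between arms", {
  set.seed(61)
  pt_ <- pc <- numeric(200)
  for (r in 1:200) {
    cl <- toy_clinical(120, pcr = rbinom(120, 1, 0.3), seed = 6000 + r)
    x <- rnorm(120)
    pt_[r] <- screen(x, cl, "treated_arm")$lr_p
    pc[r] <- screen(x, cl, "control_arm")$lr_p
  }
  expect_gt(suppressWarnings(ks.test(pt_, pc)$p.value), 0.01)
})

test_that("signature scores are centered means of member genes", {
  v <- rbind(g1 = c(1, 2, 3, 4, 10),
             g2 = c(5, 5, 5, 5, 5),
             g3 = -c(1, 2, 3, 4, 10))
  colnames(v) <- paste0("P", 1:5)
  m <- omics_matrix(v, kind = "expression")

  s1 <- signature_score(m, "g1")
  expect_equal(unname(s1), c(1, 2, 3, 4, 10) - 3)

  s13 <- signature_score(m, c("g1", "g3"))
  expect_equal(unname(s13), rep(0, 5))  # v and -v cancel after centering

  expect_message(s_all <- signature_score(m, c("g1", "g2", "g3", "gx")),
                 "absent")
  centered <- v - apply(v, 1, median)
  expect_equal(s_all, colMeans(centered))

  expect_error(signature_score(m, c("nope1", "nope2")), "no genes")
})

test_that("matrix-wide screens report per-feature rows and pass counts", {
  cfg <- sim_config(n_per_arm = 200, biomarkers = list(
    biomarker_spec("hit", beta_bm = 2),
    biomarker_spec("null1"), biomarker_spec("null2")), seed = 77)
  sim <- generate_cohort(cfg)
  co <- sim$cohort
  res <- screen_all(co$matrices$rppa, co$clinical, population = "treated_arm")
  expect_equal(nrow(res$table), 3L)
  expect_lt(res$table$lr_p[res$table$biomarker == "hit"], 0.05)
  expect_gte(res$n_pass, 1)

  empty <- omics_matrix(matrix(numeric(0), 0, nrow(co$clinical),
                               dimnames = list(character(0),
                                               co$clinical$patient_id)),
                        kind = "rppa")
  res0 <- screen_all(empty, co$clinical)
  expect_equal(nrow(res0$table), 0L)
  expect_equal(res0$n_pass, 0L)
})
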