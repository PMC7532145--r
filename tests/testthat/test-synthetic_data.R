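test_that("null-effect cohorts hit their baseline pCR rates", {
  # all effects zero, beta0 = 0: pooled pCR near 0.5
  cfg <- sim_config(n_per_arm = 1000, beta0 = 0, beta_hr = 0,
                    beta_her2 = 0, beta_trt = 0, seed = 11)
  sim <- generate_cohort(cfg)
  n <- nrow(sim$cohort$clinical)
  expect_equal(n, 2000L)
  expect_lt(abs(mean(sim$cohort$clinical$pcr) - 0.5),
            3 * sqrt(0.25 / n))
  expect_equal(sum(sim$cohort$clinical$arm == "treated"), 1000L)

  # beta0 = -1.386 -> inverse-logit about 0.2
  cfg2 <- sim_config(n_per_arm = 1000, beta0 = -1.386, beta_hr = 0,
                     beta_her2 = 0, beta_trt = 0, seed = 12)
  sim2 <- generate_cohort(cfg2)
  p0 <- plogis(-1.386)
  expect_lt(abs(mean(sim2$cohort$clinical$pcr) - p0),
            3 * sqrt(p0 * (1 - p0) / 2000))
})

test_that("marginal arm difference matches a brute-force Monte-Carlo oracle", {
  cfg <- sim_config(n_per_arm = 20000,
                    biomarkers = biomarker_spec("x", beta_bm_trt = 1.5),
                    seed = 8)
  sim <- generate_cohort(cfg)
  cl <- sim$cohort$clinical
  emp <- mean(sim$truth$p[cl$arm == "treated"]) -
    mean(sim$truth$p[cl$arm == "control"])

  # independent re-simulation of the same generative model
  set.seed(1)
  z <- rnorm(1e6)
  sub <- sample.int(4, 1e6, TRUE, prob = cfg$subtype_props)
  hr <- as.integer(sub %in% c(1, 3))
  her2 <- as.integer(sub %in% c(3, 4))
  base <- cfg$beta0 + cfg$beta_hr * hr + cfg$beta_her2 * her2
  oracle <- mean(plogis(base + cfg$beta_trt + 1.5 * z)) -
    mean(plogis(base))
  expect_lt(abs(emp - oracle), 0.01)
})

test_that("same seed is bit-identical, different seeds differ", {
  cfg <- sim_config(n_per_arm = 200,
                    biomarkers = biomarker_spec("x"), seed = 3)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort$clinical$pcr, b$cohort$clinical$pcr)
  expect_identical(a$cohort$matrices$rppa$values,
                   b$cohort$matrices$rppa$values)
  cfg2 <- cfg
  cfg2$seed <- 4
  c_ <- generate_cohort(cfg2)
  expect_false(identical(a$cohort$clinical$pcr, c_$cohort$clinical$pcr))
})

test_that("within-block correlation of latent log scores converges to rho", {
  cfg <- sim_config(n_per_arm = 1000, biomarkers = list(
    biomarker_spec("a", block = "B1", rho = 0.6),
    biomarker_spec("b", block = "B1", rho = 0.6),
    biomarker_spec("c", rho = 0)), seed = 21)
  sim <- generate_cohort(cfg)
  v <- sim$truth$pre_batch_rppa
  expect_lt(abs(cor(log(v["a", ]), log(v["b", ])) - 0.6), 0.05)
  expect_lt(abs(cor(log(v["a", ]), log(v["c", ]))), 0.08)
})

test_that("batch effects transform columns exactly as configured", {
  set.seed(2)
  v <- matrix(rlnorm(40, 9, 0.5), 4,
              dimnames = list(paste0("e", 1:4), sprintf("P%02d", 1:10)))
  m <- omics_matrix(v, kind = "rppa")
  assign1 <- setNames(rep("b1", 10), colnames(v))

  ident <- apply_rppa_batch_effects(m, assign1,
                                    list(b1 = list(shift = 0, scale = 1)))
  expect_identical(ident$values, v)

  shifted <- apply_rppa_batch_effects(m, assign1,
                                      list(b1 = list(shift = 10, scale = 1)))
  expect_identical(shifted$values, v + 10)

  assign2 <- setNames(rep(c("A", "B"), each = 5), colnames(v))
  two <- apply_rppa_batch_effects(m, assign2,
                                  list(A = list(shift = 0, scale = 1),
                                       B = list(shift = 5, scale = 2)))
  expect_equal(rowMeans(two$values[, 6:10]),
               2 * rowMeans(v[, 6:10]) + 5)
  expect_identical(attr(two, "pre_batch"), v)

  expect_error(apply_rppa_batch_effects(m, setNames(rep("zz", 10),
                                                    colnames(v)),
                                        list(A = list(shift = 0, scale = 1))),
               "unknown batch")
})

test_that("refitting the generating model recovers every coefficient", {
  cfg <- sim_config(n_per_arm = 10000,
                    biomarkers = biomarker_spec("x", beta_bm = 0.4,
                                                beta_bm_trt = 0.8),
                    seed = 31)
  sim <- generate_cohort(cfg)
  cl <- sim$cohort$clinical
  z <- sim$truth$z[cl$patient_id, "x"]
  trt <- as.numeric(cl$arm == "treated")
  X <- cbind("(Intercept)" = 1, hr = cl$hr, her2 = cl$her2, trt = trt,
             z = z, "trt:z" = trt * z)
  fit <- fit_logistic(cl$pcr, X)
  truth <- c(cfg$beta0, cfg$beta_hr, cfg$beta_her2, cfg$beta_trt, 0.4, 0.8)
  expect_true(all(abs(fit$coefficients - truth) < 0.1))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(subtype_props = c(0.5, 0.5, 0.1, 0)),
               "summing to 1")
  expect_error(biomarker_spec("x", effect = "step", delta = 1),
               "requires theta")
  expect_error(biomarker_spec("x", rho = 1), "rho")
  expect_error(sim_config(rppa_batch = list(a = list(shift = 0,
                                                     scale = -1))),
               "scale")
})

test_that("written cohorts round-trip through the plain-text readers", {
  cfg <- sim_config(n_per_arm = 30,
                    biomarkers = biomarker_spec("x"),
                    n_features_null = 3, seed = 9)
  sim <- generate_cohort(cfg)
  d <- tempfile()
  write_cohort(sim, d)
  cl <- load_clinical(file.path(d, "clinical.tsv"))
  rp <- load_matrix(file.path(d, "rppa.tsv"), kind = "rppa",
                    batch_map = file.path(d, "batches.tsv"))
  ex <- load_matrix(file.path(d, "expression.tsv"), kind = "expression")
  co <- align_cohort(cl, rppa = rp, expression = ex)
  expect_equal(nrow(co$clinical), 60L)
  expect_identical(co$matrices$rppa$values,
                   sim$cohort$matrices$rppa$values)
  expect_identical(co$matrices$expression$values,
                   sim$cohort$matrices$expression$values)
})
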