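# Trial-cohort simulator with known ground truth: two arms, four receptor
# subtypes, lognormal biomarkers with optional correlation blocks, a binary
# pCR outcome from a logistic model with treatment x biomarker effects, and
# batch effects on the protein (RPPA) matrix.

#' Specify one simulated biomarker
#'
#' Biomarkers are generated as lognormal intensities: a latent standard
#' normal score `z` (optionally sharing a block factor with other
#' biomarkers) is mapped to `exp(meanlog + sdlog * z)`, mimicking the
#' positive, right-skewed scale of protein-array endpoints. Effects on the
#' outcome come in two modes:
#' \describe{
#'   \item{linear}{adds `(beta_bm + beta_bm_trt * treated) * z` to the
#'     logit of pCR — i.e. logits per SD of log intensity;}
#'   \item{step}{adds `(delta + delta_trt * treated) * (value > theta)`,
#'     a logit jump at a raw-intensity threshold `theta`, which makes the
#'     cutpoint-search estimand well defined.}
#' }
#'
#' @param name feature id.
#' @param meanlog,sdlog lognormal log-scale location and scale; scalars or
#'   length-4 vectors ordered as HR+HER2-, TN, HR+HER2+, HR-HER2+.
#' @param effect `"linear"` or `"step"`.
#' @param beta_bm,beta_bm_trt main and treatment-interaction logits per SD
#'   of log intensity (linear mode).
#' @param theta,delta,delta_trt threshold on the raw scale and the main /
#'   treatment-interaction logit jumps (step mode).
#' @param block optional correlation-block id; biomarkers sharing a block
#'   share one latent factor.
#' @param rho within-block correlation of latent scores, |rho| < 1.
#' @param assay which matrix the feature lands in (`"rppa"` or
#'   `"expression"`; expression features are emitted on the log scale).
#' @return a `biomarker_spec` list.
#' @export
biomarker_spec <- function(name, meanlog = 9, sdlog = 0.5,
                           effect = c("linear", "step"),
                           beta_bm = 0, beta_bm_trt = 0,
                           theta = NULL, delta = NULL, delta_trt = 0,
                           block = NULL, rho = 0,
                           assay = c("rppa", "expression")) {
  effect <- match.arg(effect)
  assay <- match.arg(assay)
  if (effect == "step" && (is.null(theta) || is.null(delta)))
    stop("step mode requires theta and delta")
  if (effect == "linear" && !is.null(theta))
    stop("exactly one effect parameterization may be populated")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  meanlog <- rep_len(meanlog, 4L)
  sdlog <- rep_len(sdlog, 4L)
  if (any(sdlog <= 0)) stop("sdlog must be positive")
  structure(list(name = name, meanlog = meanlog, sdlog = sdlog,
                 effect = effect, beta_bm = beta_bm,
                 beta_bm_trt = beta_bm_trt, theta = theta, delta = delta,
                 delta_trt = delta_trt, block = block, rho = rho,
                 assay = assay),
            class = "biomarker_spec")
}

#' Simulation configuration
#'
#' Defaults emulate the neoadjuvant trial setting the package targets:
#' four receptor subtypes at the prevalences of the trial's reference
#' population (HR+HER2- 0.384, TN 0.368, HR+HER2+ 0.158, HR-HER2+ 0.09),
#' a control-arm baseline pCR around 22% with a positive treatment effect,
#' HER2+ tumors more responsive and HR+ less so, and a protein matrix
#' measured on two arrays with additive/multiplicative batch distortion.
#'
#' @param n_per_arm patients per arm (each arm gets exactly this many).
#' @param subtype_props length-4 probabilities (HR+HER2-, TN, HR+HER2+,
#'   HR-HER2+) summing to 1.
#' @param beta0 logit of baseline pCR (control arm, HR-HER2- tumor,
#'   biomarkers at reference).
#' @param beta_hr,beta_her2,beta_trt logit effects of HR+, HER2+ and
#'   treatment assignment.
#' @param biomarkers list of [biomarker_spec()] objects.
#' @param rppa_batch named list, one entry per array, each
#'   `list(shift =, scale =)`; applied to raw protein intensities as
#'   `scale * v + shift`. Patients are assigned to arrays uniformly.
#' @param n_features_null count of pure-noise log-expression features
#'   (N(8, 1), no outcome effect).
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_per_arm = 100,
                       subtype_props = c(0.384, 0.368, 0.158, 0.09),
                       beta0 = stats::qlogis(0.22),
                       beta_hr = -0.8, beta_her2 = 0.6, beta_trt = 0.6,
                       biomarkers = list(),
                       rppa_batch = list(array1 = list(shift = 0, scale = 1),
                                         array2 = list(shift = 1000,
                                                       scale = 1.25)),
                       n_features_null = 0, seed = 1) {
  if (length(subtype_props) != 4L || any(subtype_props < 0) ||
      any(subtype_props > 1) || abs(sum(subtype_props) - 1) > 1e-9)
    stop("subtype_props must be 4 probabilities summing to 1")
  if (inherits(biomarkers, "biomarker_spec")) biomarkers <- list(biomarkers)
  for (b in rppa_batch)
    if (b$scale <= 0) stop("batch scale factors must be > 0")
  structure(list(n_per_arm = n_per_arm, subtype_props = subtype_props,
                 beta0 = beta0, beta_hr = beta_hr, beta_her2 = beta_her2,
                 beta_trt = beta_trt, biomarkers = biomarkers,
                 rppa_batch = rppa_batch,
                 n_features_null = n_features_null, seed = seed),
            class = "sim_config")
}

#' Apply per-batch location/scale distortion to a matrix
#'
#' Transforms each patient's column as `v -> scale_b * v + shift_b` for the
#' patient's batch. The untouched input is retained as attribute
#' `"pre_batch"` (simulation ground truth for standardization tests).
#'
#' @param matrix an `omics_matrix`.
#' @param assignment named patient -> batch character vector covering all
#'   columns.
#' @param config named list batch -> `list(shift =, scale =)`.
#' @return an `omics_matrix` with `batch` set and the distortion applied.
#' @export
apply_rppa_batch_effects <- function(matrix, assignment, config) {
  stopifnot(inherits(matrix, "omics_matrix"))
  assignment <- assignment[colnames(matrix$values)]
  if (anyNA(assignment)) stop("batch assignment missing for some patients")
  unknown <- setdiff(unique(assignment), names(config))
  if (length(unknown)) stop("unknown batch: ", fmt_ids(unknown))
  v <- matrix$values
  for (b in names(config)) {
    j <- which(assignment == b)
    if (length(j))
      v[, j] <- config[[b]]$scale * v[, j] + config[[b]]$shift
  }
  out <- omics_matrix(v, kind = matrix$kind, batch = assignment)
  attr(out, "pre_batch") <- matrix$values
  out
}

#' Generate a synthetic trial cohort with known ground truth
#'
#' Draws a clinical table (arms of exactly `n_per_arm`, multinomial
#' subtypes), biomarker matrices per [biomarker_spec()] with correlated
#' blocks built from one shared latent Gaussian factor per block, and a
#' binary pCR outcome from the logistic model
#' `logit P(pCR) = beta0 + beta_hr*HR + beta_her2*HER2 + beta_trt*treated
#' + sum(biomarker effects)`. Batch effects from `config$rppa_batch` are
#' applied to the protein matrix; the pre-batch matrix and every generating
#' coefficient are recorded in the returned `truth`.
#'
#' @param config a [sim_config()].
#' @return list with `cohort` (a `cohort`) and `truth` (list: coefficients,
#'   per-biomarker effect parameters and latent scores `z`, per-patient
#'   linear predictor `eta` and success probability `p`, batch assignment,
#'   pre-batch protein matrix).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_per_arm
    N <- 2L * n
    ids <- sprintf("P%05d", seq_len(N))
    arm <- rep(c("control", "treated"), each = n)
    trt <- as.integer(arm == "treated")
    sub_idx <- sample.int(4L, N, replace = TRUE, prob = config$subtype_props)
    subtype <- SUBTYPES[sub_idx]
    hr <- as.integer(sub_idx %in% c(1L, 3L))
    her2 <- as.integer(sub_idx %in% c(3L, 4L))
    # MP class is annotation only: independent of outcome by construction
    mp <- sample(c("MP1", "MP2"), N, replace = TRUE)

    eta <- config$beta0 + config$beta_hr * hr + config$beta_her2 * her2 +
      config$beta_trt * trt

    bms <- config$biomarkers
    blocks <- unique(unlist(lapply(bms, `[[`, "block")))
    factors <- if (length(blocks)) {
      f <- matrix(stats::rnorm(N * length(blocks)), N)
      colnames(f) <- blocks
      f
    }
    zmat <- vmat <- matrix(NA_real_, N, length(bms))
    assay <- character(length(bms))
    for (i in seq_along(bms)) {
      b <- bms[[i]]
      eps <- stats::rnorm(N)
      z <- if (!is.null(b$block))
        sqrt(b$rho) * factors[, b$block] + sqrt(1 - b$rho) * eps
      else eps
      v <- exp(b$meanlog[sub_idx] + b$sdlog[sub_idx] * z)
      if (b$effect == "linear") {
        eta <- eta + (b$beta_bm + b$beta_bm_trt * trt) * z
      } else {
        eta <- eta + (b$delta + b$delta_trt * trt) * as.numeric(v > b$theta)
      }
      zmat[, i] <- z
      vmat[, i] <- v
      assay[i] <- b$assay
    }
    if (length(bms)) {
      colnames(zmat) <- colnames(vmat) <- vapply(bms, `[[`, "", "name")
      rownames(zmat) <- rownames(vmat) <- ids
    }

    p <- stats::plogis(eta)
    pcr <- stats::rbinom(N, 1L, p)
    clinical <- new_clinical_table(ids, arm, hr, her2, mp, pcr)

    mats <- list()
    batch_assign <- NULL
    pre_batch <- NULL
    if (any(assay == "rppa")) {
      raw <- t(vmat[, assay == "rppa", drop = FALSE])
      rppa <- omics_matrix(raw, kind = "rppa")
      batch_assign <- stats::setNames(
        sample(names(config$rppa_batch), N, replace = TRUE), ids)
      rppa <- apply_rppa_batch_effects(rppa, batch_assign, config$rppa_batch)
      pre_batch <- attr(rppa, "pre_batch")
      mats$rppa <- rppa
    }
    expr_rows <- NULL
    if (any(assay == "expression"))
      expr_rows <- t(log(vmat[, assay == "expression", drop = FALSE]))
    if (config$n_features_null > 0) {
      nullm <- matrix(stats::rnorm(config$n_features_null * N, 8, 1),
                      config$n_features_null, N)
      rownames(nullm) <- sprintf("null%05d", seq_len(config$n_features_null))
      colnames(nullm) <- ids
      expr_rows <- rbind(expr_rows, nullm)
    }
    if (!is.null(expr_rows))
      mats$expression <- omics_matrix(expr_rows, kind = "expression")

    cohort <- structure(list(clinical = clinical, matrices = mats,
                             dropped = list(clinical = character(0))),
                        class = "cohort")
    truth <- list(beta0 = config$beta0, beta_hr = config$beta_hr,
                  beta_her2 = config$beta_her2, beta_trt = config$beta_trt,
                  biomarkers = bms, z = zmat, eta = eta, p = p,
                  subtype = subtype, batch = batch_assign,
                  pre_batch_rppa = pre_batch)
    list(cohort = cohort, truth = truth)
  })
}

#' Write a simulated cohort to a directory of delimited files
#'
#' Emits `clinical.tsv`, plus `rppa.tsv`/`expression.tsv` and `batches.tsv`
#' as present, and `truth.json` with the scalar generating coefficients —
#' the file layout the analysis drivers consume.
#'
#' @param sim result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_clinical(sim$cohort$clinical, file.path(dir, "clinical.tsv"))
  for (nm in names(sim$cohort$matrices))
    write_matrix(sim$cohort$matrices[[nm]],
                 file.path(dir, paste0(nm, ".tsv")))
  if (!is.null(sim$truth$batch)) {
    utils::write.table(
      data.frame(patient_id = names(sim$truth$batch),
                 batch = unname(sim$truth$batch)),
      file.path(dir, "batches.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  scalars <- sim$truth[c("beta0", "beta_hr", "beta_her2", "beta_trt")]
  scalars$biomarkers <- lapply(sim$truth$biomarkers, unclass)
  jsonlite::write_json(scalars, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
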