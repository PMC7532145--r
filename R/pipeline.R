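# Orchestration: the pre-specified screening report (the dotplot table)
# and the cutpoint -> Bayesian subgroup chain, with deterministic
# per-stage seeds derived from one master seed.

PRESPECIFIED_COLUMNS <- list(
  list(population = "treated_arm",          subset = "all"),
  list(population = "control_arm",          subset = "all"),
  list(population = "interaction",          subset = "all"),
  list(population = "interaction_adjusted", subset = "all"),
  list(population = "treated_arm",          subset = "HER2+"),
  list(population = "treated_arm",          subset = "TN"),
  list(population = "treated_arm",          subset = "HR+HER2-"))

#' Run the pre-specified association screen over listed biomarkers
#'
#' For every biomarker, fits the seven model/population columns of the
#' association dotplots — treated arm (all), control arm (all), treatment
#' interaction, receptor-adjusted interaction, and the treated arm within
#' the HER2+, TN and HR+HER2- subsets — and returns one tidy row per
#' biomarker x column with direction, LR p and `-log10(p)`. Biomarkers
#' absent from the matrix are reported in the `"skipped"` attribute and
#' the run continues. Underpowered or separated cells carry flags, not
#' errors.
#'
#' @param cohort an aligned `cohort`.
#' @param assay name of the matrix in `cohort$matrices` to read biomarkers
#'   from.
#' @param biomarkers character vector of feature ids (default: all
#'   features of the matrix).
#' @return data.frame of association rows with attribute `"skipped"`.
#' @export
run_prespecified <- function(cohort, assay = "rppa", biomarkers = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  mat <- cohort$matrices[[assay]]
  if (is.null(mat)) stop("cohort has no matrix named '", assay, "'")
  v <- mat$values[, cohort$clinical$patient_id, drop = FALSE]
  biomarkers <- biomarkers %||% rownames(v)
  skipped <- setdiff(biomarkers, rownames(v))
  found <- setdiff(biomarkers, skipped)
  rows <- list()
  for (bm in found) {
    for (col in PRESPECIFIED_COLUMNS) {
      rows[[length(rows) + 1L]] <-
        screen(v[bm, ], cohort$clinical, population = col$population,
               subset = col$subset, id = bm)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(biomarker = character(0), population = character(0),
               subset = character(0), direction = integer(0),
               lr_p = numeric(0), n = integer(0), n_pcr = integer(0),
               flags = character(0), stringsAsFactors = FALSE)
  tab$neg_log10_p <- -log10(tab$lr_p)
  attr(tab, "skipped") <- skipped
  tab
}

#' Chain cutpoint discovery into Bayesian subgroup estimation
#'
#' Runs [cv_cutpoint_search()] on one endpoint within the treated arm of
#' the chosen receptor subset; if a stable cutpoint is found, dichotomizes
#' the whole cohort at it, samples the 8-term Bayesian subgroup model on
#' all patients with the endpoint measured, and returns posterior pCR-rate
#' estimates for the biomarker-high and biomarker-low treated patients of
#' the subset, along with the fraction of the subset classified high. If
#' the stability filter fails the chain stops with status
#' `"no stable cutpoint"` and no Bayes stage.
#'
#' Stage seeds are derived deterministically from `seed` via
#' [derive_seed()], so rerunning one stage reproduces the full run.
#'
#' @param cohort an aligned `cohort`.
#' @param endpoint feature id in the assay matrix.
#' @param assay matrix name (default `"rppa"`).
#' @param subset `"all"`, `"HER2+"`, `"TN"` or `"HR+HER2-"`.
#' @param n_repeats CV repeats for the cutpoint search.
#' @param stability_rule passed to [cv_cutpoint_search()].
#' @param bayes_spec a [bayes_model_spec()]; its seed is overridden by the
#'   derived stage seed.
#' @param seed master seed.
#' @return a `cutpoint_bayes_result`: `status`, `cutpoint`
#'   (`cutpoint_result`), and when the filter passes `posterior`,
#'   `estimate_high`, `estimate_low`, `fraction_high`, `n_subset`.
#' @export
run_cutpoint_bayes <- function(cohort, endpoint, assay = "rppa",
                               subset = "all", n_repeats = 500,
                               stability_rule = "selected",
                               bayes_spec = bayes_model_spec(),
                               seed = 1) {
  stopifnot(inherits(cohort, "cohort"))
  mat <- cohort$matrices[[assay]]
  if (is.null(mat)) stop("cohort has no matrix named '", assay, "'")
  if (!endpoint %in% rownames(mat$values))
    stop("endpoint '", endpoint, "' not in matrix '", assay, "'")
  cl <- cohort$clinical
  values <- mat$values[endpoint, cl$patient_id]

  in_subset <- subset_rows(cl, subset)
  search_rows <- in_subset & cl$arm == "treated" & !is.na(values)
  cp <- cv_cutpoint_search(values[search_rows], cl$pcr[search_rows],
                           n_repeats = n_repeats,
                           stability_rule = stability_rule,
                           seed = derive_seed(seed, "cutpoint"),
                           endpoint = endpoint)
  if (!cp$pass_stability)
    return(structure(list(status = "no stable cutpoint", cutpoint = cp,
                          endpoint = endpoint, subset = subset),
                     class = "cutpoint_bayes_result"))

  measured <- !is.na(values)
  bm_bin <- dichotomize(values[measured], cp$selected)
  cl_m <- cl[measured, , drop = FALSE]
  X <- build_design(cl_m, bm_bin)
  bayes_spec$seed <- derive_seed(seed, "bayes")
  post <- sample_posterior(X, cl_m$pcr, bayes_spec)

  sub_m <- subset_rows(cl_m, subset)
  treated_m <- cl_m$arm == "treated"
  est_hi <- subset_pcr_estimate(post, X, sub_m & treated_m & bm_bin == 1L,
                                label = paste0(subset, "/", endpoint,
                                               "-high, treated"))
  est_lo <- subset_pcr_estimate(post, X, sub_m & treated_m & bm_bin == 0L,
                                label = paste0(subset, "/", endpoint,
                                               "-low, treated"))
  structure(list(status = "ok", cutpoint = cp, posterior = post,
                 estimate_high = est_hi, estimate_low = est_lo,
                 fraction_high = mean(bm_bin[sub_m] == 1L),
                 n_subset = sum(sub_m), endpoint = endpoint,
                 subset = subset),
            class = "cutpoint_bayes_result")
}

#' @export
print.cutpoint_bayes_result <- function(x, ...) {
  cat(sprintf("cutpoint->Bayes chain [%s, %s]: %s\n", x$endpoint, x$subset,
              x$status))
  if (x$status == "ok") {
    cat(sprintf("  cutpoint %.6g; %.0f%% of subset classified high\n",
                x$cutpoint$selected, 100 * x$fraction_high))
    print(x$estimate_high)
    print(x$estimate_low)
  }
  invisible(x)
}

#' Write an association table as TSV
#' @param table data.frame from [run_prespecified()] or [screen_all()].
#' @param path output path.
#' @export
write_association_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
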