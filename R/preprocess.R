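# Cross-array RPPA standardization by subtype-balanced resampling, and the
# 2-of-3 variant-caller consensus filter.

# Per-subtype resample quotas by largest-remainder rounding; ties broken by
# the fixed subtype order (HR+HER2-, TN, HR+HER2+, HR-HER2+), which is the
# input order — order() is stable so no extra handling is needed.
subtype_quotas <- function(size, props) {
  raw <- size * props
  base <- floor(raw)
  short <- size - sum(base)
  if (short > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Standardize an RPPA matrix across arrays by balanced resampling
#'
#' Each array (batch) is standardized independently before the columns are
#' recombined. Within a batch, `n_resamples` bootstrap samples of the
#' batch's own size are drawn with replacement under per-subtype quotas that
#' hold the receptor-subtype mix at `target_props` (largest-remainder
#' rounding); for every endpoint the mean and SD within each resample are
#' computed and averaged across resamples, and the endpoint is z-scored
#' with those averaged parameters: `(v - mean_of_means) / mean_of_sds`.
#'
#' A subtype with a nonzero target but no patients in a batch has its quota
#' redistributed proportionally over the subtypes present (with a warning).
#' Endpoints constant within a batch (mean of SDs = 0) are flagged and set
#' to missing for that batch rather than divided.
#'
#' @param matrix an `omics_matrix` with a `batch` label per patient (a
#'   single unnamed batch is assumed if absent).
#' @param clinical aligned `clinical_table` supplying each patient's
#'   receptor subtype.
#' @param target_props length-4 subtype proportions (HR+HER2-, TN,
#'   HR+HER2+, HR-HER2+) to balance on; default is the trial reference
#'   population mix.
#' @param n_resamples bootstrap draws per batch (default 5000).
#' @param seed integer RNG seed.
#' @return list with `matrix` (standardized `omics_matrix`) and `params`
#'   (data.frame per batch x endpoint: `mean_of_means`, `mean_of_sds`,
#'   `flagged`).
#' @export
rppa_standardize <- function(matrix, clinical,
                             target_props = c(0.384, 0.368, 0.158, 0.09),
                             n_resamples = 5000, seed = 1) {
  stopifnot(inherits(matrix, "omics_matrix"))
  if (length(target_props) != 4L || abs(sum(target_props) - 1) > 1e-9)
    stop("target_props must be 4 probabilities summing to 1")
  pts <- colnames(matrix$values)
  sub <- clinical$subtype[match(pts, clinical$patient_id)]
  if (anyNA(sub)) stop("every patient in the matrix needs a clinical subtype")
  batch <- matrix$batch %||% stats::setNames(rep("batch1", length(pts)), pts)

  out <- matrix$values
  params <- NULL
  with_seed(seed, {
    for (b in unique(batch)) {
      j <- which(batch == b)
      M <- matrix$values[, j, drop = FALSE]
      size <- length(j)
      idx_by_sub <- lapply(seq_len(4L), function(s)
        which(as.integer(sub[j]) == s))
      present <- vapply(idx_by_sub, length, integer(1L)) > 0
      props <- target_props
      if (any(!present & props > 0)) {
        warning(sprintf(
          "batch '%s': subtype(s) %s absent; quota redistributed", b,
          paste(SUBTYPES[!present & props > 0], collapse = ", ")))
        props[!present] <- 0
        props <- props / sum(props)
      }
      q <- subtype_quotas(size, props)

      sum_m <- sum_s <- numeric(nrow(M))
      for (r in seq_len(n_resamples)) {
        take <- unlist(lapply(seq_len(4L), function(s) {
          if (q[s] == 0L) return(integer(0))
          pool <- idx_by_sub[[s]]
          pool[sample.int(length(pool), q[s], replace = TRUE)]
        }), use.names = FALSE)
        S <- M[, take, drop = FALSE]
        ok <- !is.na(S)
        nn <- rowSums(ok)
        S0 <- S
        S0[!ok] <- 0
        m <- rowSums(S0) / nn
        ss <- rowSums(S0^2) - nn * m^2
        sdv <- sqrt(pmax(ss, 0) / pmax(nn - 1, 1))
        sum_m <- sum_m + m
        sum_s <- sum_s + sdv
      }
      mu <- sum_m / n_resamples
      sg <- sum_s / n_resamples
      flagged <- !is.finite(sg) | sg <= 0
      std <- (M - mu) / ifelse(flagged, NA_real_, sg)
      std[flagged, ] <- NA_real_
      out[, j] <- std
      params <- rbind(params, data.frame(
        batch = b, endpoint = rownames(M), mean_of_means = mu,
        mean_of_sds = sg, flagged = flagged, row.names = NULL,
        stringsAsFactors = FALSE))
    }
  })
  list(matrix = omics_matrix(out, kind = matrix$kind, batch = matrix$batch),
       params = params)
}

#' Write standardization parameters as a JSON sidecar
#'
#' Emulates the endpoint -> (mean, sd) parameter files deposited alongside
#' normalized RPPA matrices.
#'
#' @param params the `params` element of [rppa_standardize()]'s result.
#' @param path output path.
#' @export
write_standardization_params <- function(params, path) {
  by_batch <- split(params, params$batch)
  obj <- lapply(by_batch, function(df)
    stats::setNames(lapply(seq_len(nrow(df)), function(i)
      list(mean = df$mean_of_means[i], sd = df$mean_of_sds[i],
           flagged = df$flagged[i])), df$endpoint))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Consensus filter over multiple variant callers
#'
#' Retains exactly the (patient, gene, variant) triples reported by at
#' least `min_support` distinct callers — the "two or more callers" rule
#' used to pool somatic calls from independent pipelines.
#'
#' @param callsets named list, one data.frame per caller with columns
#'   `patient_id`, `gene`, `variant_key`.
#' @param n_callers total number of callers (default `length(callsets)`).
#' @param min_support minimum distinct callers supporting a call
#'   (default 2).
#' @return data.frame `patient_id`, `gene`, `variant_key`,
#'   `n_callers_supporting` (all `>= min_support`).
#' @export
consensus_mutations <- function(callsets, n_callers = length(callsets),
                                min_support = 2) {
  if (min_support > n_callers)
    stop("min_support (", min_support, ") exceeds n_callers (",
         n_callers, ")")
  if (is.null(names(callsets)) || anyDuplicated(names(callsets)))
    stop("callsets must carry distinct caller names")
  empty <- data.frame(patient_id = character(0), gene = character(0),
                      variant_key = character(0),
                      n_callers_supporting = integer(0),
                      stringsAsFactors = FALSE)
  if (length(callsets) == 0L) return(empty)
  per <- lapply(names(callsets), function(cl) {
    df <- callsets[[cl]]
    stopifnot(all(c("patient_id", "gene", "variant_key") %in% names(df)))
    if (nrow(df) == 0L) return(NULL)
    # a caller supports a triple at most once
    unique(data.frame(patient_id = as.character(df$patient_id),
                      gene = as.character(df$gene),
                      variant_key = as.character(df$variant_key),
                      stringsAsFactors = FALSE))
  })
  all_calls <- do.call(rbind, per)
  if (is.null(all_calls) || nrow(all_calls) == 0L) return(empty)
  key <- paste(all_calls$patient_id, all_calls$gene, all_calls$variant_key,
               sep = "\r")
  support <- table(key)
  keep_keys <- names(support)[support >= min_support]
  if (length(keep_keys) == 0L) return(empty)
  first <- all_calls[match(keep_keys, key), , drop = FALSE]
  first$n_callers_supporting <- as.integer(support[keep_keys])
  first <- first[order(first$patient_id, first$gene, first$variant_key), ,
                 drop = FALSE]
  rownames(first) <- NULL
  first
}

#' Read per-caller variant lists from TSV files
#'
#' @param paths named character vector of file paths (names are caller
#'   ids); each file has columns `patient_id`, `gene`, `variant_key`.
#' @return named list of data.frames for [consensus_mutations()].
#' @export
load_callsets <- function(paths) {
  if (is.null(names(paths))) stop("paths must be named by caller")
  lapply(paths, function(p)
    utils::read.table(p, header = TRUE, sep = "\t",
                      colClasses = "character", stringsAsFactors = FALSE))
}
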