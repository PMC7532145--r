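# Domain containers and delimited-text I/O for clinical tables and
# feature-by-patient omics matrices, plus cohort alignment.

SUBTYPES <- c("HR+HER2-", "TN", "HR+HER2+", "HR-HER2+")

#' Receptor subtype from HR and HER2 status
#'
#' Maps binary hormone-receptor and HER2 status to the four receptor
#' subtypes used throughout: HR+HER2-, TN (triple negative, HR-HER2-),
#' HR+HER2+ and HR-HER2+.
#'
#' @param hr,her2 binary (0/1) vectors.
#' @return factor with levels `c("HR+HER2-", "TN", "HR+HER2+", "HR-HER2+")`.
#' @export
subtype_from_receptors <- function(hr, her2) {
  stopifnot(length(hr) == length(her2))
  idx <- ifelse(hr == 1,
                ifelse(her2 == 1, 3L, 1L),
                ifelse(her2 == 1, 4L, 2L))
  factor(SUBTYPES[idx], levels = SUBTYPES)
}

#' Default column dialect for clinical tables
#'
#' Maps the canonical field names to the column names found in a delimited
#' file, and declares which raw values encode each arm. Override entries to
#' read files with other headers.
#'
#' @param patient_id,arm,hr,her2,mp_class,pcr column names in the file.
#' @param control_values,treated_values raw strings recognized as each arm.
#' @return named list used by [load_clinical()].
#' @export
clinical_dialect <- function(patient_id = "patient_id", arm = "arm",
                             hr = "hr", her2 = "her2",
                             mp_class = "mp_class", pcr = "pcr",
                             control_values = c("control", "ctr", "0"),
                             treated_values = c("treated", "trt", "1")) {
  list(patient_id = patient_id, arm = arm, hr = hr, her2 = her2,
       mp_class = mp_class, pcr = pcr,
       control_values = control_values, treated_values = treated_values)
}

new_clinical_table <- function(patient_id, arm, hr, her2, mp_class, pcr) {
  df <- data.frame(patient_id = as.character(patient_id),
                   arm = factor(arm, levels = c("control", "treated")),
                   hr = as.integer(hr), her2 = as.integer(her2),
                   mp_class = factor(mp_class,
                                     levels = c("MP1", "MP2", "unknown")),
                   pcr = as.integer(pcr),
                   stringsAsFactors = FALSE)
  df$subtype <- subtype_from_receptors(df$hr, df$her2)
  if (anyDuplicated(df$patient_id)) {
    dup <- unique(df$patient_id[duplicated(df$patient_id)])
    stop("duplicate patient_id: ", fmt_ids(dup))
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a clinical table from delimited text
#'
#' Reads a TSV/CSV file with one row per patient carrying trial arm, HR and
#' HER2 status, MammaPrint class and the binary pCR outcome. Rows whose arm
#' or pCR value cannot be parsed are excluded with a message; their count is
#' recorded in the `"dropped"` attribute.
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (`.csv` is comma, anything else tab).
#' @param dialect column-name map from [clinical_dialect()].
#' @return a `clinical_table` data.frame with columns `patient_id`, `arm`,
#'   `hr`, `her2`, `mp_class`, `pcr` and a derived 4-level `subtype`.
#' @export
load_clinical <- function(path, dialect = clinical_dialect()) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("patient_id", "arm", "hr", "her2", "pcr")
  for (f in need) {
    if (!dialect[[f]] %in% names(raw))
      stop("missing required column '", dialect[[f]], "' (field ", f, ")")
  }
  arm_raw <- tolower(trimws(raw[[dialect$arm]]))
  arm <- ifelse(arm_raw %in% tolower(dialect$control_values), "control",
         ifelse(arm_raw %in% tolower(dialect$treated_values), "treated",
                NA_character_))
  pcr <- suppressWarnings(as.integer(raw[[dialect$pcr]]))
  pcr[!pcr %in% c(0L, 1L)] <- NA_integer_
  hr <- suppressWarnings(as.integer(raw[[dialect$hr]]))
  her2 <- suppressWarnings(as.integer(raw[[dialect$her2]]))
  mp <- if (dialect$mp_class %in% names(raw)) raw[[dialect$mp_class]]
        else rep("unknown", nrow(raw))
  mp[!mp %in% c("MP1", "MP2")] <- "unknown"

  bad <- is.na(arm) | is.na(pcr) | !hr %in% c(0L, 1L) | !her2 %in% c(0L, 1L)
  if (any(bad))
    message("load_clinical: excluded ", sum(bad),
            " row(s) with unparseable arm/pcr/receptor values")
  keep <- !bad
  tab <- new_clinical_table(raw[[dialect$patient_id]][keep], arm[keep],
                            hr[keep], her2[keep], mp[keep], pcr[keep])
  attr(tab, "dropped") <- raw[[dialect$patient_id]][bad]
  tab
}

#' Construct an omics matrix container
#'
#' A features-by-patients numeric matrix with an assay kind and an optional
#' per-patient batch label. Missing values are explicit `NA`, never silent
#' zeros.
#'
#' @param values numeric matrix, features in rows (rownames required),
#'   patients in columns (colnames required).
#' @param kind `"expression"` (log-scale) or `"rppa"` (raw intensity).
#' @param batch optional named character vector, patient -> batch label.
#' @return an `omics_matrix` object.
#' @export
omics_matrix <- function(values, kind = c("expression", "rppa"),
                         batch = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("values must have feature rownames and patient colnames")
  if (is.null(colnames(values)))
    colnames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature_ids: ",
         fmt_ids(unique(rownames(values)[duplicated(rownames(values))])))
  if (!is.null(batch)) {
    if (is.null(names(batch))) stop("batch must be a named patient->label vector")
    batch <- batch[colnames(values)]
    if (anyNA(batch)) stop("batch label missing for some patients")
  }
  structure(list(values = values, batch = batch, kind = kind),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d patients, %d missing\n",
              x$kind, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Read a features-by-patients matrix from delimited text
#'
#' First column holds feature ids, remaining columns one patient each.
#' Empty cells become explicit `NA`; any non-numeric non-empty cell is a
#' fatal error reported with its coordinates.
#'
#' @param path file path (`.csv` comma, otherwise tab).
#' @inheritParams omics_matrix
#' @param batch_map optional named patient->batch vector, or path to a
#'   two-column (patient, batch) TSV.
#' @return an `omics_matrix`.
#' @export
load_matrix <- function(path, kind = c("expression", "rppa"),
                        batch_map = NULL) {
  kind <- match.arg(kind)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  feats <- raw[[1L]]
  if (anyDuplicated(feats))
    stop("duplicated feature row: ",
         fmt_ids(unique(feats[duplicated(feats)])))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells[trimws(cells) == ""] <- NA_character_
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- is.na(vals) & !is.na(cells)
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell '%s' at feature '%s', patient '%s'",
                 cells[bad][1L], feats[ij[1L]], colnames(cells)[ij[2L]]))
  }
  rownames(vals) <- feats
  colnames(vals) <- colnames(cells)
  if (is.character(batch_map) && length(batch_map) == 1L &&
      file.exists(batch_map)) {
    bm <- utils::read.table(batch_map, header = TRUE, sep = "\t",
                            colClasses = "character")
    batch_map <- stats::setNames(bm[[2L]], bm[[1L]])
  }
  omics_matrix(vals, kind = kind, batch = batch_map)
}

#' Write an omics matrix as tab-delimited text
#'
#' Inverse of [load_matrix()]: finite entries round-trip bit-identically
#' (values are written with full precision), `NA` as empty cells.
#'
#' @param x an `omics_matrix`.
#' @param path output path.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  v <- x$values
  chr <- array(vapply(v, function(z) {
    if (is.na(z)) "" else format(z, digits = 17, scientific = FALSE)
  }, character(1L)), dim = dim(v))
  df <- data.frame(feature_id = rownames(v), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", colnames(v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a clinical table as tab-delimited text
#' @param clinical a `clinical_table`.
#' @param path output path.
#' @export
write_clinical <- function(clinical, path) {
  df <- as.data.frame(clinical)[, c("patient_id", "arm", "hr", "her2",
                                    "mp_class", "pcr")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align clinical and omics patient sets into a cohort
#'
#' Intersects the patient sets of the clinical table and every supplied
#' matrix, orders patients lexicographically by id (so all downstream
#' seeded procedures are order-stable), and records per-source lists of
#' dropped patient ids.
#'
#' @param clinical a `clinical_table`.
#' @param ... named `omics_matrix` objects (at least one).
#' @return a `cohort`: list with `clinical`, `matrices` (named list) and
#'   `dropped` (named list of patient ids removed per source).
#' @export
align_cohort <- function(clinical, ...) {
  mats <- list(...)
  if (length(mats) == 0L) stop("at least one matrix is required")
  if (is.null(names(mats)) || any(names(mats) == ""))
    stop("matrices must be named")
  for (m in mats) stopifnot(inherits(m, "omics_matrix"))

  sets <- c(list(clinical = clinical$patient_id),
            lapply(mats, function(m) colnames(m$values)))
  common <- Reduce(intersect, sets)
  if (length(common) == 0L) stop("empty patient intersection across sources")
  common <- sort(common)

  dropped <- lapply(sets, function(s) sort(setdiff(s, common)))
  cl <- clinical[match(common, clinical$patient_id), , drop = FALSE]
  rownames(cl) <- NULL
  class(cl) <- c("clinical_table", "data.frame")
  mats <- lapply(mats, function(m) {
    v <- m$values[, common, drop = FALSE]
    omics_matrix(v, kind = m$kind,
                 batch = if (!is.null(m$batch)) m$batch[common])
  })
  structure(list(clinical = cl, matrices = mats, dropped = dropped),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d patients (%d treated / %d control), %d pCR\n",
              nrow(x$clinical), sum(x$clinical$arm == "treated"),
              sum(x$clinical$arm == "control"), sum(x$clinical$pcr)))
  for (nm in names(x$matrices))
    cat(sprintf("  %s: %d features [%s]\n", nm,
                nrow(x$matrices[[nm]]$values), x$matrices[[nm]]$kind))
  nd <- vapply(x$dropped, length, integer(1L))
  if (any(nd > 0))
    cat("  dropped:", paste(sprintf("%s=%d", names(nd), nd), collapse = ", "),
        "\n")
  invisible(x)
}

#' Per-stage patient accounting for a cohort
#'
#' Consort-style counts: patients per source, the aligned intersection and
#' per-source dropped counts, so no patient is silently lost.
#'
#' @param cohort a `cohort`.
#' @return data.frame with columns `source`, `n_input`, `n_kept`, `n_dropped`.
#' @export
consort_counts <- function(cohort) {
  n_kept <- nrow(cohort$clinical)
  nd <- vapply(cohort$dropped, length, integer(1L))
  data.frame(source = names(cohort$dropped),
             n_input = n_kept + nd, n_kept = n_kept, n_dropped = nd,
             row.names = NULL, stringsAsFactors = FALSE)
}
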