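# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded package functions never perturb the
#' global random stream.
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# x * log(y) with the 0 * log(0) = 0 convention used in multinomial
# log-likelihoods.
xlogy <- function(x, y) {
  out <- numeric(length(x))
  nz <- !is.na(x) & x != 0
  out[nz] <- x[nz] * log(y[nz])
  out[is.na(x)] <- NA_real_
  out
}

#' Derive a per-stage child seed from a master seed
#'
#' Deterministic hash of (master seed, stage name), kept below 2^31 so the
#' result is a valid R integer seed. Used by the pipeline so that rerunning
#' a single stage with its derived seed reproduces the full-pipeline run.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 1000003
  as.integer((abs(as.numeric(master)) %% 1000003) * 1009 + h) %% 2147483647L
}

fmt_ids <- function(x, max = 5L) {
  if (length(x) > max) paste(c(x[seq_len(max)], "..."), collapse = ", ")
  else paste(x, collapse = ", ")
}
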