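# Hypergeometric over-representation analysis with Benjamini-Hochberg
# correction, plus a GMT gene-set reader.

#' Read gene sets from a GMT file
#'
#' Standard tab-delimited GMT: set id, description, then member genes.
#' Duplicate members within a set are dropped.
#'
#' @param path GMT file path.
#' @return named list of character vectors (names carry the description
#'   as attribute `"description"`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("malformed GMT line (need id, description, >=1 gene): ",
           substr(ln, 1, 40))
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    attr(members, "description") <- parts[2L]
    sets[[parts[1L]]] <- members
  }
  sets
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1),
#' order-equivariant in its input.
#'
#' @param ps numeric p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(ps) {
  if (any(ps < 0 | ps > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(ps, method = "BH")
}

#' Hypergeometric over-representation of gene sets in a hit list
#'
#' For each set, `p = P[X >= n_overlap]` with `X` hypergeometric (drawing
#' `n_hits` from a universe of `n_universe` containing `n_set` set
#' members); one-sided over-representation only. Sets are intersected with
#' the universe before testing, and BH adjustment is applied across the
#' tested sets.
#'
#' @param hits character vector of hit gene ids (must lie in `universe`;
#'   strays are dropped with a warning).
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param universe character vector of background gene ids.
#' @return data.frame: `set_id`, `n_universe`, `n_hits`, `n_set`,
#'   `n_overlap`, `p`, `p_bh`.
#' @export
hypergeom_enrich <- function(hits, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  hits <- unique(hits)
  stray <- setdiff(hits, universe)
  if (length(stray)) {
    warning(length(stray), " hit(s) outside the universe dropped")
    hits <- intersect(hits, universe)
  }
  N <- length(universe)
  n <- length(hits)
  res <- lapply(names(gene_sets), function(id) {
    set <- intersect(unique(gene_sets[[id]]), universe)
    K <- length(set)
    k <- length(intersect(set, hits))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, n_universe = N, n_hits = n, n_set = K,
               n_overlap = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bh <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}
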