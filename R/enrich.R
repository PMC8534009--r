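#' Read a GMT gene-set annotation file
#'
#' GMT format: one gene set per line, tab-separated fields `name`,
#' `description`, then member genes.
#'
#' @param path path to a .gmt file.
#' @return A named list of character vectors of gene ids; the descriptions
#'   are kept in the `"description"` attribute.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2L)
  sets
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' For each annotation term, tests over-representation of `geneSet` among
#' the term's genes within `universe` by the one-sided hypergeometric upper
#' tail
#' \deqn{p = P(X \ge k) = \sum_{i \ge k} \frac{\binom{K}{i}\binom{N-K}{n-i}}
#'   {\binom{N}{n}},}
#' where N is the universe size, K the term size (within the universe), n
#' the query-set size and k the overlap. P-values are Benjamini-Hochberg
#' adjusted across terms. Empty terms get p = 1.
#'
#' @param geneSet character vector of query genes (must be a subset of
#'   `universe`; genes outside it are dropped with a warning).
#' @param termSets named list of character vectors (e.g. from [readGmt()]).
#' @param universe character vector of all testable genes; defaults to the
#'   union of all term genes intersected with a supplied `tested` set, or
#'   simply the union of term genes.
#' @param tested optional character vector of genes actually measured, used
#'   to restrict the default universe.
#' @return A data.frame with one row per term: `term`, `term_size`,
#'   `overlap`, `p`, `fdr`, and the overlapping gene ids in
#'   `overlap_genes` (comma-separated).
#' @examples
#' sets <- list(T1 = sprintf("g%d", 1:4))
#' enrichHyper(sprintf("g%d", 1:5), sets, universe = sprintf("g%d", 1:20))
#' @export
enrichHyper <- function(geneSet, termSets, universe = NULL, tested = NULL) {
  if (is.null(universe)) {
    universe <- unique(unlist(termSets))
    if (!is.null(tested)) universe <- intersect(universe, tested)
  }
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  drop <- setdiff(geneSet, universe)
  if (length(drop))
    warning(length(drop), " query gene(s) outside the universe were dropped")
  geneSet <- unique(intersect(geneSet, universe))
  n <- length(geneSet)
  N <- length(universe)

  rows <- lapply(names(termSets), function(nm) {
    term <- intersect(termSets[[nm]], universe)
    K <- length(term)
    ov <- intersect(geneSet, term)
    k <- length(ov)
    p <- if (K == 0L || n == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = nm, term_size = K, overlap = k, p = p,
               overlap_genes = paste(ov, collapse = ","))
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, "BH")
  out[order(out$p), c("term", "term_size", "overlap", "p", "fdr",
                      "overlap_genes")]
}
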