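#' Term overrepresentation by the hypergeometric test with BH FDR
#'
#' For each term with at least one study gene, tests overrepresentation of
#' the term in the study set against the universe with the upper-tail
#' hypergeometric probability `P(X >= k)` and controls FDR with
#' Benjamini-Hochberg. Terms with no study gene are suppressed: they carry
#' no evidence and only inflate the test count.
#'
#' @param study non-empty character vector, a subset of `universe`.
#' @param term_map two-column data.frame (gene_id, term); a gene may carry
#'   several terms.
#' @param universe character vector of all gene IDs.
#' @param fdr significance level on the adjusted q (default 0.01).
#' @return data.frame sorted by p: `term`, `k`, `n`, `K`, `N`, `p_value`,
#'   `q_value`, `significant`.
#' @export
hypergeom_enrichment <- function(study, term_map, universe, fdr = 0.01) {
  study <- unique(study)
  universe <- unique(universe)
  if (length(study) == 0L) stop("study set is empty")
  if (length(setdiff(study, universe)) > 0L)
    stop("study set must be a subset of the universe")
  tm <- term_map[term_map[[1L]] %in% universe, , drop = FALSE]
  genes_by_term <- split(as.character(tm[[1L]]), as.character(tm[[2L]]))
  n <- length(study)
  N <- length(universe)
  rows <- lapply(names(genes_by_term), function(term) {
    tg <- unique(genes_by_term[[term]])
    k <- length(intersect(study, tg))
    if (k == 0L) return(NULL)
    K <- length(tg)
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, n = n, K = K, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      q_value = numeric(), significant = logical()))
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- out$q_value <= fdr
  out[order(out$p_value), , drop = FALSE]
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment; input p-values must lie in `(0, 1]`.
#'
#' @param pvals numeric vector of p-values.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvals, method = "BH")
}
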