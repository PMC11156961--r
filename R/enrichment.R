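#' Hypergeometric over-representation test
#'
#' One-sided (enrichment-only) exact test of the overlap between a query and
#' a gene set against an explicit background universe of size N: with K set
#' members in the background, a query of size n and k hits,
#' p = P(X >= k) for X ~ Hypergeometric(N, K, n), and
#' fold = (k/n) / (K/N). Query genes absent from the background are dropped
#' with a warning; the set is intersected with the background first. All
#' symbols are normalized with [norm_symbol()].
#'
#' @param query character vector of query symbols.
#' @param gene_set character vector of set members (or a one-element named
#'   list as returned by [read_gmt()]).
#' @param background character vector: the explicit universe.
#' @param set_name label for the output row.
#' @return one-row data.frame: `set_name`, `k`, `n`, `K`, `N`, `fold`,
#'   `pvalue`.
#' @export
hypergeom_enrich <- function(query, gene_set, background, set_name = "set") {
  if (is.list(gene_set)) {
    set_name <- names(gene_set)[1] %||% set_name
    gene_set <- gene_set[[1]]
  }
  background <- unique(norm_symbol(background))
  if (!length(background)) stopf("empty background")
  query <- unique(norm_symbol(query))
  outside <- setdiff(query, background)
  if (length(outside)) {
    warnf("%d query gene(s) absent from the background were dropped", length(outside))
    query <- intersect(query, background)
  }
  members <- intersect(unique(norm_symbol(gene_set)), background)
  N <- length(background)
  K <- length(members)
  n <- length(query)
  k <- length(intersect(query, members))
  fold <- if (n > 0 && K > 0) (k / n) / (K / N) else 0
  p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(set_name = set_name, k = k, n = n, K = K, N = N,
             fold = fold, pvalue = p, stringsAsFactors = FALSE)
}

#' Batch over-representation analysis with BH FDR
#'
#' Applies [hypergeom_enrich()] to every set and adjusts p-values across
#' sets with Benjamini-Hochberg.
#'
#' @param query character vector of query symbols.
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param background explicit universe.
#' @return data.frame with one row per set, ordered by p-value, plus `fdr`.
#' @export
ora_batch <- function(query, sets, background) {
  if (!length(sets)) stopf("no gene sets supplied")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stopf("gene sets must be named")
  }
  if (anyDuplicated(names(sets))) {
    stopf("duplicate set names: %s",
          paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  background <- unique(norm_symbol(background))
  query_in <- intersect(unique(norm_symbol(query)), background)
  res <- do.call(rbind, lapply(names(sets), function(nm) {
    suppressWarnings(
      hypergeom_enrich(query_in, sets[[nm]], background, set_name = nm)
    )
  }))
  res$fdr <- adjust_multiplicity(res$pvalue, "BH")
  res[order(res$pvalue, res$set_name), , drop = FALSE]
}
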