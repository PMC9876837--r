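# Local over-representation analysis: hypergeometric upper-tail tests of a
# query gene list against a gene-set collection within a measured universe,
# with BH false-discovery-rate adjustment per category.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated genes when `n` genes are drawn without
#' replacement from a universe of `N` genes of which `K` are annotated.
#' Evaluated on the log scale via [stats::phyper] for numerical stability.
#'
#' @param k overlap count(s), `0 <= k <= min(n, K)`.
#' @param n query size in the universe.
#' @param K gene-set size in the universe.
#' @param N universe size.
#' @return the upper-tail probability, in `(0, 1]`.
#' @export
hypergeomTest <- function(k, n, K, N) {
  if (any(k < 0) || any(n < 0) || any(K < 0) || any(N < 1)) {
    stop("counts must be nonnegative and N >= 1")
  }
  if (any(k > pmin(n, K)) || any(n > N) || any(K > N)) {
    stop("inconsistent counts: need k <= min(n, K) and n, K <= N")
  }
  # P(X >= k) = 1 - P(X <= k - 1), computed as an upper tail in log space
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE,
                    log.p = TRUE))
}

#' Over-representation analysis against a gene-set collection
#'
#' Tests each gene set for over-representation of the query within the
#' measured universe (all genes surviving probe collapsing is the intended
#' universe). Query genes outside the universe are ignored with a warning;
#' set members outside the universe do not count. BH adjustment is applied
#' across all tested sets (those with at least one universe member) within
#' each category, matching how per-category FDRs are reported; only sets
#' overlapping the query are returned.
#'
#' @param query character vector of query gene symbols.
#' @param collection a [GeneSetCollection-class].
#' @param universe character vector of measured gene symbols.
#' @return a [S4Vectors::DataFrame] sorted by p value with columns
#'   `category`, `term`, `k` (overlap), `n` (query size), `K` (set size),
#'   `N` (universe size), `percent` (overlap as percent of the query),
#'   `p`, `fdr`, `genes` (comma-separated overlap).
#' @export
enrichGeneSets <- function(query, collection, universe) {
  stopifnot(methods::is(collection, "GeneSetCollection"))
  universe <- unique(trimws(universe))
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(trimws(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query genes outside the universe ignored")
  }
  query <- intersect(query, universe)
  N <- length(universe)
  n <- length(query)
  sets <- geneSets(collection)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    hit <- intersect(query, members)
    S4Vectors::DataFrame(
      category = collection@category[[nm]],
      term = nm, k = length(hit), n = n, K = K, N = N,
      percent = if (n > 0) 100 * length(hit) / n else 0,
      p = hypergeomTest(length(hit), n, K, N),
      genes = paste(sort(hit), collapse = ","))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(S4Vectors::DataFrame(category = character(), term = character(),
                                k = integer(), n = integer(), K = integer(),
                                N = integer(), percent = numeric(),
                                p = numeric(), fdr = numeric(),
                                genes = character()))
  }
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  for (cat in unique(out$category)) {
    i <- out$category == cat
    out$fdr[i] <- bhAdjust(out$p[i])
  }
  out <- out[out$k >= 1L, ]
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}
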