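# Kim-Park entropy scoring of the NMF basis, metagene membership
# screening, and activation-based metagene ranking.

#' Kim-Park metagene-specificity scores
#'
#' For each gene the loadings are row-normalized to contributions
#' `p(i,q) = W(i,q) / sum_q' W(i,q')` and scored as
#' `S(i) = 1 + (1 / log2 r) * sum_q p(i,q) log2 p(i,q)` (with
#' `0 log 0 := 0`). `S = 1` iff the gene loads on exactly one metagene and
#' `S = 0` iff its loading is uniform; the score is invariant to positive
#' rescaling of the row.
#'
#' @param W nonnegative basis matrix (genes by metagenes), `r >= 2`
#'   columns.
#' @return a named numeric vector of scores in `[0, 1]`; rows with an
#'   all-zero loading get `NA` (flagged with a warning).
#' @export
kimParkScores <- function(W) {
  W <- as.matrix(W)
  if (any(W < 0)) stop("W must be nonnegative")
  r <- ncol(W)
  if (r < 2L) stop("Kim-Park score needs at least 2 metagenes (log2 r = 0)")
  rs <- rowSums(W)
  zero <- rs == 0
  if (any(zero)) {
    warning(sum(zero), " genes with all-zero loading: score undefined")
  }
  p <- W / ifelse(rs == 0, NA_real_, rs)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  s <- 1 + rowSums(plogp) / log2(r)
  s[zero] <- NA_real_
  stats::setNames(pmin(pmax(s, 0), 1), rownames(W))
}

#' Screen metagene member genes
#'
#' Retains gene `i` iff its score exceeds `median(S) + 3 * MAD(S)`
#' (robust Kim-Park screening; `mean(S) + 3 * SD(S)` behind
#' `rule = "sd"`) and its largest loading exceeds the median of all entries
#' of `W`. Each retained gene is assigned to its argmax metagene (ties to
#' the lowest index); metagenes keeping fewer than 2 members are dropped.
#'
#' @param W nonnegative basis matrix (genes by metagenes).
#' @param scores per-gene scores from [kimParkScores()]; computed if
#'   missing.
#' @param rule `"mad"` (default, robust) or `"sd"` threshold rule.
#' @return a [MetageneSet-class]; empty (with a warning) when no gene
#'   passes.
#' @export
selectMetageneGenes <- function(W, scores = NULL, rule = c("mad", "sd")) {
  W <- as.matrix(W)
  rule <- match.arg(rule)
  if (is.null(scores)) scores <- kimParkScores(W)
  ok <- !is.na(scores)
  thr <- if (rule == "mad") {
    stats::median(scores[ok]) + 3 * stats::mad(scores[ok])
  } else {
    mean(scores[ok]) + 3 * stats::sd(scores[ok])
  }
  wmax <- apply(W, 1L, max)
  keep <- ok & scores > thr & wmax > stats::median(W)
  assigned <- max.col(W, ties.method = "first")
  rs <- rowSums(W)
  sel <- which(keep)
  members <- S4Vectors::DataFrame(
    gene = if (is.null(rownames(W))) as.character(sel) else rownames(W)[sel],
    metagene = assigned[sel],
    loading = W[cbind(sel, assigned[sel])],
    contribution = W[cbind(sel, assigned[sel])] / rs[sel],
    score = unname(scores[sel]))
  # drop metagenes with fewer than 2 surviving members
  tab <- table(members$metagene)
  small <- as.integer(names(tab)[tab < 2L])
  members <- members[!(members$metagene %in% small), ]
  if (nrow(members) == 0L) warning("no metagene member passed the screen")
  activation <- vapply(seq_len(ncol(W)), function(q) {
    sum(members$loading[members$metagene == q])
  }, numeric(1))
  methods::new("MetageneSet",
               members = members,
               activation = activation,
               metagene_order = order(-activation, seq_along(activation)),
               n_metagenes = ncol(W))
}

#' Rank metagenes by activation
#'
#' Orders metagenes by activation (sum of member loadings) in descending
#' order, ties to the lower original index, and sorts the members of each
#' metagene by loading in descending order. A `metagene_rank` and a
#' within-metagene `member_rank` column are added so that a top-`k` member
#' report can be extracted directly.
#'
#' @param set a [MetageneSet-class].
#' @param top number of members per metagene kept in the top report
#'   attached as `metadata(memberTable(x))$top` (default 15).
#' @return the reordered [MetageneSet-class].
#' @export
rankMetagenes <- function(set, top = 15L) {
  stopifnot(methods::is(set, "MetageneSet"))
  if (nrow(set@members) == 0L) stop("empty metagene set")
  ord <- set@metagene_order
  rank_of <- stats::setNames(seq_along(ord), ord)
  mem <- set@members
  mrank <- as.integer(rank_of[as.character(mem$metagene)])
  o <- order(mrank, -mem$loading, mem$gene)
  mem <- mem[o, ]
  mem$metagene_rank <- mrank[o]
  mem$member_rank <- stats::ave(seq_len(nrow(mem)), mem$metagene,
                                FUN = seq_along)
  topmem <- mem[mem$member_rank <= top, ]
  S4Vectors::metadata(mem)$top <- topmem
  methods::initialize(set, members = mem)
}

#' Top member genes per metagene
#'
#' @param set a ranked [MetageneSet-class] (see [rankMetagenes()]).
#' @param n members per metagene (default 15).
#' @return a [S4Vectors::DataFrame] of the top members.
#' @export
topMembers <- function(set, n = 15L) {
  mem <- memberTable(set)
  if (!"member_rank" %in% colnames(mem)) set <- rankMetagenes(set, top = n)
  mem <- memberTable(set)
  mem[mem$member_rank <= n, ]
}
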