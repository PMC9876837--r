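# Nonnegative matrix factorization by multiplicative updates (Frobenius
# objective), multi-restart RSS-versus-rank scans, and unit-invariant
# knee-point rank selection. The update loop runs in compiled code
# (src/nmf_updates.cpp).

#' @useDynLib MetageneNMF, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Build the NMF target matrix from selected DEGs
#'
#' Restricts the gene-level log2 expression matrix to the selected DEG rows
#' (all samples). If any entry is negative, the global minimum is
#' subtracted so the target is nonnegative (shift logged and recorded as
#' the `"shift"` attribute).
#'
#' @param dataset a gene-level [ExpressionDataset-class].
#' @param degs a DEG table from [selectDEGs()] or a character vector of
#'   gene symbols.
#' @return a nonnegative numeric matrix, genes by samples.
#' @export
buildTarget <- function(dataset, degs) {
  stopifnot(methods::is(dataset, "ExpressionDataset"))
  genes <- if (is.character(degs)) degs else degs$gene
  if (length(genes) == 0L) stop("the DEG list is empty")
  genes <- intersect(genes, rownames(dataset))
  if (length(genes) == 0L) stop("no DEG found in the dataset rows")
  V <- SummarizedExperiment::assay(dataset)[genes, , drop = FALSE]
  shift <- 0
  if (min(V) < 0) {
    shift <- min(V)
    V <- V - shift
    .msg("target matrix shifted by %.4f to enforce nonnegativity", -shift)
  }
  attr(V, "shift") <- shift
  V
}

#' Fit an NMF by multiplicative updates
#'
#' Minimizes the Frobenius objective `||V - WH||_F^2` with Lee-Seung
#' multiplicative updates `H <- H * (W'V) / (W'WH + eps)` and
#' `W <- W * (VH') / (WHH' + eps)`, `eps = 1e-12`. Factors are initialized
#' with i.i.d. uniform(0, 1] entries scaled by `mean(V) / r`, under `seed`.
#' Iteration stops when the relative RSS decrease falls below `tol` or
#' after `max_iter` iterations; the objective is non-increasing at every
#' recorded iteration.
#'
#' @param V nonnegative target matrix (genes by samples).
#' @param r factorization rank, `1 <= r <= min(dim(V))` (rank scans use
#'   `r >= 2`).
#' @param seed integer seed for the initialization.
#' @param max_iter maximum number of update iterations (default 2000).
#' @param tol relative RSS-decrease convergence threshold (default 1e-5).
#' @return a [Factorization-class].
#' @export
nmfFit <- function(V, r, seed = 1L, max_iter = 2000L, tol = 1e-5) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be nonnegative")
  r <- .assertCount(r, "r", min = 1L)
  if (r > min(dim(V))) stop("rank exceeds min(dim(V))")
  n <- nrow(V); m <- ncol(V)
  sc <- mean(V) / r
  init <- withSeed(seed, list(
    W = matrix(stats::runif(n * r), n, r) * sc,
    H = matrix(stats::runif(r * m), r, m) * sc))
  fit <- .nmf_mu_cpp(V, init$W, init$H, as.integer(max_iter),
                     as.numeric(tol))
  W <- fit$W; H <- fit$H
  rownames(W) <- rownames(V)
  colnames(H) <- colnames(V)
  methods::new("Factorization", W = W, H = H, r = r,
               rss = max(fit$rss, 0),
               rss_trace = pmax(fit$trace, 0), n_iter = fit$n_iter,
               seed = as.integer(seed), converged = fit$converged)
}

#' Scan factorization ranks
#'
#' Fits the NMF at every rank of the grid with `n_restarts` seeded restarts
#' (seeds `base_seed + 0 .. n_restarts - 1`) and records the best (lowest)
#' RSS per rank.
#'
#' @param V nonnegative target matrix.
#' @param rank_grid strictly increasing integer ranks within
#'   `[2, min(dim(V))]`; at least 2 values (>= 3 for a knee).
#' @param n_restarts seeded restarts per rank (default 10).
#' @param base_seed base seed; restart `i` uses `base_seed + i - 1`.
#' @param max_iter,tol per-fit convergence settings (see [nmfFit()]); the
#'   scan default of 500 iterations resolves the curve shape at a fraction
#'   of the full-fit cost.
#' @return a [RankCurve-class] with `chosen_rank` unset.
#' @export
rankScan <- function(V, rank_grid = 3:30, n_restarts = 10L, base_seed = 1L,
                     max_iter = 500L, tol = 1e-5) {
  V <- as.matrix(V)
  rank_grid <- as.integer(rank_grid)
  if (length(rank_grid) < 2L) {
    stop("rank grid of length 1: the knee is undefined; provide >= 3 ranks")
  }
  if (any(diff(rank_grid) <= 0L)) stop("rank grid must be strictly increasing")
  if (min(rank_grid) < 2L || max(rank_grid) > min(dim(V))) {
    stop("rank grid must lie within [2, min(dim(V))]; ",
         "use a smaller grid or more DEG rows")
  }
  rss <- vapply(rank_grid, function(r) {
    min(vapply(seq_len(n_restarts), function(i) {
      nmfFit(V, r, seed = base_seed + i - 1L,
             max_iter = max_iter, tol = tol)@rss
    }, numeric(1)))
  }, numeric(1))
  methods::new("RankCurve", ranks = rank_grid, rss = rss,
               chosen_rank = NA_integer_,
               n_restarts = as.integer(n_restarts))
}

#' Unit-invariant knee of a decreasing curve
#'
#' Both axes are min-max scaled to `[0, 1]`; for each interior point the
#' distance to the chord joining the first and last scaled points is
#' computed, and the abscissa of the maximum distance is returned (ties
#' broken toward the smaller abscissa). The scaling makes the result
#' invariant to affine rescaling of either axis.
#'
#' @param x,y coordinates of the curve (at least 3 points, `y` not all
#'   equal).
#' @param method `"perpendicular"` (default) for the perpendicular distance
#'   to the chord, `"vertical"` for the vertical deviation from it.
#' @return the value of `x` at the knee.
#' @export
kneePoint <- function(x, y, method = c("perpendicular", "vertical")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need at least 3 curve points")
  }
  if (diff(range(y)) == 0) stop("flat curve has no knee")
  xs <- (x - min(x)) / diff(range(x))
  ys <- (y - min(y)) / diff(range(y))
  x1 <- xs[1]; y1 <- ys[1]
  x2 <- xs[length(xs)]; y2 <- ys[length(ys)]
  if (method == "perpendicular") {
    d <- abs((y2 - y1) * xs - (x2 - x1) * ys + x2 * y1 - y2 * x1) /
      sqrt((y2 - y1)^2 + (x2 - x1)^2)
  } else {
    chord <- y1 + (y2 - y1) * (xs - x1) / (x2 - x1)
    d <- abs(chord - ys)
  }
  d[c(1L, length(d))] <- -Inf  # knee must be interior
  if (max(d) < 1e-10) {
    stop("curve is linear (no curvature): knee undefined")
  }
  x[which.max(d)]  # which.max ties -> first (smaller x)
}

#' Knee-point rank selection on a rank curve
#'
#' @param curve a [RankCurve-class].
#' @param method distance convention, see [kneePoint()].
#' @return the selected rank (integer).
#' @export
uikKnee <- function(curve, method = c("perpendicular", "vertical")) {
  stopifnot(methods::is(curve, "RankCurve"))
  as.integer(kneePoint(curve@ranks, curve@rss, method = match.arg(method)))
}

#' Scan ranks and select the knee
#'
#' Runs [rankScan()] followed by [uikKnee()] and records the chosen rank on
#' the curve.
#'
#' @inheritParams rankScan
#' @param method knee distance convention, see [kneePoint()].
#' @return a [RankCurve-class] with `chosen_rank` set.
#' @export
selectRank <- function(V, rank_grid = 3:30, n_restarts = 10L,
                       base_seed = 1L, max_iter = 500L, tol = 1e-5,
                       method = c("perpendicular", "vertical")) {
  curve <- rankScan(V, rank_grid = rank_grid, n_restarts = n_restarts,
                    base_seed = base_seed, max_iter = max_iter, tol = tol)
  curve@chosen_rank <- uikKnee(curve, method = match.arg(method))
  curve
}
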