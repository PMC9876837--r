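# Two-group differential expression: low-intensity filtering, probe-to-
# symbol collapsing, (moderated) t statistics with empirical-Bayes variance
# shrinkage, Benjamini-Hochberg adjustment and DEG selection.

#' Remove low-intensity probes
#'
#' Drops probes whose median log2 intensity falls strictly below the given
#' quantile of all probe medians; ties at the cutoff are retained. This is
#' the array analogue of a low-count filter and improves detection
#' sensitivity downstream.
#'
#' @param dataset an [ExpressionDataset-class].
#' @param quantile cutoff quantile in `[0, 1)` of the probe-median
#'   distribution (default 0.2).
#' @return the filtered [ExpressionDataset-class].
#' @export
filterLowExpression <- function(dataset, quantile = 0.2) {
  stopifnot(methods::is(dataset, "ExpressionDataset"))
  if (quantile < 0 || quantile >= 1) stop("quantile must be in [0, 1)")
  m <- SummarizedExperiment::assay(dataset)
  med <- apply(m, 1L, stats::median)
  cut <- stats::quantile(med, quantile, names = FALSE)
  keep <- med >= cut
  if (!any(keep)) stop("low-expression filter would remove all probes")
  .msg("low-expression filter removed %d of %d probes", sum(!keep),
       length(keep))
  dataset[keep, ]
}

#' Collapse probes to gene symbols
#'
#' Probes sharing an official gene symbol are combined by arithmetic mean;
#' unannotated probes are dropped (count logged). The result is keyed by
#' gene symbol.
#'
#' @param dataset an [ExpressionDataset-class] with probe annotation.
#' @return an [ExpressionDataset-class] with one row per gene symbol.
#' @export
collapseProbes <- function(dataset) {
  stopifnot(methods::is(dataset, "ExpressionDataset"))
  symbols <- probeAnnotation(dataset)
  keep <- !is.na(symbols)
  if (!any(keep)) stop("no annotated probes to collapse")
  if (any(!keep)) .msg("dropped %d unannotated probes", sum(!keep))
  m <- SummarizedExperiment::assay(dataset)[keep, , drop = FALSE]
  sym <- symbols[keep]
  collapsed <- rowsum(m, group = sym, reorder = TRUE)
  counts <- table(sym)
  collapsed <- collapsed / as.vector(counts[rownames(collapsed)])
  out <- ExpressionDataset(collapsed, sampleGroups(dataset),
                           stats::setNames(rownames(collapsed),
                                           rownames(collapsed)))
  S4Vectors::metadata(out) <- S4Vectors::metadata(dataset)
  out
}

# Newton inversion of the trigamma function (solve trigamma(x) = y).
trigammaInverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi)) return(if (yi > 0) NaN else Inf)
    if (yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}

# Moment-matching fit of the scaled inverse-chi-square prior for gene-wise
# variances: matches mean and variance of log s^2 against the theoretical
# moments of a scaled F distribution, giving prior df d0 and prior variance
# s0^2. Returns d0 = Inf when the observed spread of log s^2 is at or below
# the pure-sampling spread.
fitVariancePrior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) {
    # too few informative variances to fit a prior: no shrinkage
    warning("fewer than two positive gene variances; ",
            "moderation disabled")
    return(list(df_prior = 0, var_prior = NA_real_))
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigammaInverse(evar)
    s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- exp(emean)
  }
  list(df_prior = d0, var_prior = s0)
}

#' Moderated two-sample t statistics
#'
#' Per-gene equal-variance pooled two-sample t between `case` and `control`
#' samples, with optional empirical-Bayes moderation: gene-wise pooled
#' variances `s_g^2` (df `d_g = n1 + n2 - 2`) are shrunk toward a prior
#' `s0^2` with prior df `d0`, estimated by moment matching on `log s_g^2`,
#' giving `s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)` and
#' `t = logFC / (s~_g sqrt(1/n1 + 1/n2))` on `d0 + d_g` degrees of freedom.
#' With `moderation = FALSE` this reduces to the ordinary pooled t.
#'
#' @param dataset a gene-level [ExpressionDataset-class] (see
#'   [collapseProbes()]) with at least 2 samples per group.
#' @param moderation logical; shrink gene-wise variances (default `TRUE`).
#' @return a [S4Vectors::DataFrame] sorted by p value with columns `gene`,
#'   `logFC` (case minus control, log2), `t`, `p`, `p_adj` (BH), `direction`
#'   (`up` iff `logFC > 0`), `mean_expr`; the fitted prior is in
#'   `metadata()`.
#' @export
moderatedT <- function(dataset, moderation = TRUE) {
  stopifnot(methods::is(dataset, "ExpressionDataset"))
  groups <- sampleGroups(dataset)
  m <- SummarizedExperiment::assay(dataset)
  case <- m[, groups == "case", drop = FALSE]
  ctrl <- m[, groups == "control", drop = FALSE]
  n1 <- ncol(ctrl); n2 <- ncol(case)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 samples per group")
  dg <- n1 + n2 - 2
  logfc <- rowMeans(case) - rowMeans(ctrl)
  ss <- rowSums((ctrl - rowMeans(ctrl))^2) +
    rowSums((case - rowMeans(case))^2)
  s2 <- ss / dg
  scale <- sqrt(1 / n1 + 1 / n2)
  if (moderation) {
    prior <- fitVariancePrior(s2, dg)
    d0 <- prior$df_prior
    s2_tilde <- if (d0 == 0) {
      s2
    } else if (is.finite(d0)) {
      (d0 * prior$var_prior + dg * s2) / (d0 + dg)
    } else {
      rep(prior$var_prior, length(s2))
    }
    df_total <- d0 + dg
  } else {
    if (all(s2 == 0)) {
      stop("all gene variances are zero; ordinary t undefined ",
           "(use moderation)")
    }
    prior <- list(df_prior = 0, var_prior = NA_real_)
    s2_tilde <- s2
    df_total <- dg
  }
  tstat <- ifelse(logfc == 0, 0, logfc / (sqrt(s2_tilde) * scale))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[logfc == 0] <- 1
  out <- S4Vectors::DataFrame(
    gene = rownames(m),
    logFC = unname(logfc),
    t = unname(tstat),
    p = unname(p),
    p_adj = bhAdjust(unname(p)),
    direction = ifelse(logfc > 0, "up", "down"),
    mean_expr = unname(rowMeans(m)))
  out <- out[order(out$p, out$gene), ]
  rownames(out) <- NULL
  S4Vectors::metadata(out) <- list(df_prior = prior$df_prior,
                                   var_prior = prior$var_prior,
                                   df_residual = dg,
                                   n_control = n1, n_case = n2)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, capped at 1, preserving input
#' order.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return the adjusted vector.
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p values must be numeric in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed genes
#'
#' Retains genes with `p < p_cut` (raw p by default; BH-adjusted with
#' `use_adjusted = TRUE`) and `|logFC| > lfc_cut`, both strict inequalities.
#'
#' @param table a DEG table from [moderatedT()].
#' @param p_cut p-value threshold (default 0.05).
#' @param lfc_cut absolute log2-fold-change threshold (default 0.5).
#' @param use_adjusted filter on the BH-adjusted p value instead of the raw
#'   p value.
#' @return the selected subset, same columns and ordering.
#' @export
selectDEGs <- function(table, p_cut = 0.05, lfc_cut = 0.5,
                       use_adjusted = FALSE) {
  if (p_cut <= 0 || lfc_cut < 0) stop("thresholds must be positive")
  pv <- if (use_adjusted) table$p_adj else table$p
  keep <- pv < p_cut & abs(table$logFC) > lfc_cut
  out <- table[keep, ]
  if (nrow(out) == 0L) {
    warning("no genes pass the DEG thresholds")
  } else {
    .msg("selected %d DEGs (%d up, %d down)", nrow(out),
         sum(out$direction == "up"), sum(out$direction == "down"))
  }
  out
}
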