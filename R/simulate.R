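# Synthetic-data generator with planted ground truth. Every pipeline input
# (expression matrix, groups, annotation, gene sets, interactome,
# gene-disease and TF-target tables) can be generated with known planted
# DE genes, planted factorization rank and planted network hubs, so each
# downstream stage has a recoverable answer.

#' Create a simulation configuration
#'
#' Defaults emulate a two-group brain microarray study: 15 control vs 18
#' case samples (5 vs 6 donors across three cell types), 218 planted
#' up-regulated and 780 planted down-regulated genes, planted rank 10.
#'
#' @param n_genes number of gene symbols.
#' @param probe_dist probabilities that a gene is measured by 1, 2 or 3
#'   probes (duplicate probes share the symbol, with independent noise).
#' @param n_samples_per_group `c(n_control, n_case)`.
#' @param n_de_up,n_de_down planted up-/down-regulated gene counts.
#' @param de_logfc_range interval the planted `|log2 FC|` values are drawn
#'   from.
#' @param r_true planted factorization rank (>= 2).
#' @param noise_sd probe-level additive Gaussian noise sd, log2 units
#'   (truncated so intensities stay nonnegative).
#' @param sample_effect_sd sd of the per-sample variation of metagene
#'   activation profiles; this is what makes the planted rank identifiable
#'   beyond the two group means.
#' @param baseline_range interval of per-metagene baseline activations
#'   (log2 units; keeps all planted intensities above ~4).
#' @param overlap_frac maximum share of a DE gene's loading carried by a
#'   second metagene of the same direction (per-gene shares are uniform on
#'   `[0, overlap_frac]`, so membership is non-exclusive and specificity
#'   varies continuously).
#' @param n_unannotated decoy probes with no gene-symbol annotation.
#' @param network_n_nodes,network_hub_degree,n_hubs synthetic interactome
#'   size, guaranteed hub degree and number of planted hubs.
#' @param seed integer seed for all generator randomness.
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(n_genes = 1500,
                             probe_dist = c(0.6, 0.3, 0.1),
                             n_samples_per_group = c(15, 18),
                             n_de_up = 218,
                             n_de_down = 780,
                             de_logfc_range = c(0.7, 1.7),
                             r_true = 10,
                             noise_sd = 0.2,
                             sample_effect_sd = 0.3,
                             baseline_range = c(7, 10),
                             overlap_frac = 0.35,
                             n_unannotated = 10,
                             network_n_nodes = 800,
                             network_hub_degree = 30,
                             n_hubs = 6,
                             seed = 1) {
  methods::new("SimulationConfig",
    n_genes = .assertCount(n_genes, "n_genes"),
    probe_dist = as.numeric(probe_dist),
    n_samples_per_group = vapply(n_samples_per_group, .assertCount,
                                 integer(1), name = "n_samples_per_group"),
    n_de_up = .assertCount(n_de_up, "n_de_up"),
    n_de_down = .assertCount(n_de_down, "n_de_down"),
    de_logfc_range = .assertRange(de_logfc_range, "de_logfc_range"),
    r_true = .assertCount(r_true, "r_true", min = 2L),
    noise_sd = .assertNonneg(noise_sd, "noise_sd"),
    sample_effect_sd = .assertNonneg(sample_effect_sd, "sample_effect_sd"),
    baseline_range = .assertRange(baseline_range, "baseline_range"),
    overlap_frac = .assertNonneg(overlap_frac, "overlap_frac"),
    n_unannotated = .assertCount(n_unannotated, "n_unannotated", min = 0L),
    network_n_nodes = .assertCount(network_n_nodes, "network_n_nodes"),
    network_hub_degree = .assertCount(network_hub_degree,
                                      "network_hub_degree"),
    n_hubs = .assertCount(n_hubs, "n_hubs", min = 0L),
    seed = .assertCount(seed, "seed", min = 0L)
  )
}

#' Simulate a two-group expression dataset with planted structure
#'
#' Generates a log2-intensity probe-by-sample matrix as `V = W H + noise`
#' with a block-sparse nonnegative planted basis `W`. The `r_true` metagene
#' blocks partition the planted DE genes: up-blocks carry a case activation
#' offset of +1, down-blocks of -1, and a DE gene's loading equals its
#' planted `|log2 FC|`, so its case-minus-control mean difference is exactly
#' the planted value. Null genes load equally on one up-block and one
#' down-block so their planted group difference cancels to exactly zero
#' while the signal matrix keeps rank `r_true`. Each DE gene carries a
#' random share (up to `overlap_frac`) of its loading on a second block of
#' the same direction, giving non-exclusive membership with a continuous
#' specificity spectrum. Activation profiles vary between samples
#' (`sample_effect_sd`, group-centred), which is what makes the planted rank
#' recoverable from the residual-sum-of-squares curve.
#'
#' @param config a [SimulationConfig-class].
#' @param gene_symbols optional symbols to reuse (e.g. to share a gene
#'   universe across two simulated datasets).
#' @param pinned_lfc optional named numeric of signed planted log2 fold
#'   changes forced onto specific genes (used to share DE genes across
#'   datasets).
#' @param de_exclude genes excluded from the randomly drawn DE sets
#'   (pinned genes are still used).
#' @return a list with elements `dataset` ([ExpressionDataset-class]) and
#'   `truth` ([GroundTruth-class]).
#' @export
simulateExpression <- function(config, gene_symbols = NULL,
                               pinned_lfc = NULL,
                               de_exclude = character()) {
  stopifnot(methods::is(config, "SimulationConfig"))
  methods::validObject(config)
  n <- config@n_genes
  n1 <- config@n_samples_per_group[1]
  n2 <- config@n_samples_per_group[2]
  m <- n1 + n2
  r <- config@r_true
  if (r > min(n, m)) {
    stop("r_true exceeds min(n_genes, total samples)")
  }
  withSeed(config@seed, {
    symbols <- if (is.null(gene_symbols)) sprintf("G%05d", seq_len(n)) else {
      if (length(gene_symbols) != n) stop("gene_symbols length != n_genes")
      gene_symbols
    }
    pinned_lfc <- pinned_lfc[names(pinned_lfc) %in% symbols]
    pin_up <- names(pinned_lfc)[pinned_lfc > 0]
    pin_dn <- names(pinned_lfc)[pinned_lfc < 0]
    pool <- setdiff(symbols, unique(c(de_exclude, names(pinned_lfc))))
    need_up <- config@n_de_up - length(pin_up)
    need_dn <- config@n_de_down - length(pin_dn)
    if (need_up < 0 || need_dn < 0) {
      stop("more pinned genes than planted DE slots")
    }
    if (need_up + need_dn > length(pool)) {
      stop("not enough eligible genes for the requested DE counts")
    }
    draw <- sample(pool, need_up + need_dn)
    de_up <- c(pin_up, draw[seq_len(need_up)])
    de_dn <- c(pin_dn, draw[need_up + seq_len(need_dn)])
    null_genes <- setdiff(symbols, c(de_up, de_dn))

    # blocks: up-blocks first (lower indices), then down-blocks
    alloc <- .apportion(r, c(up = length(de_up), down = length(de_dn)))
    if (alloc["up"] > length(de_up) || alloc["down"] > length(de_dn)) {
      stop("r_true too large for the planted DE counts")
    }
    up_blocks <- seq_len(alloc["up"])
    dn_blocks <- alloc["up"] + seq_len(alloc["down"])
    d_q <- c(rep(1, alloc["up"]), rep(-1, alloc["down"]))

    # planted |logFC|: hubs drawn from the upper part of the range
    lfc_abs <- stats::setNames(
      stats::runif(length(c(de_up, de_dn)),
                   config@de_logfc_range[1], config@de_logfc_range[2]),
      c(de_up, de_dn))
    hubs <- character()
    if (config@n_hubs > 0L) {
      hubs <- if (length(pin_up) >= config@n_hubs) {
        pin_up[seq_len(config@n_hubs)]
      } else {
        .resample(de_up, min(config@n_hubs, length(de_up)))
      }
      lfc_abs[hubs] <- stats::runif(length(hubs),
                                    mean(config@de_logfc_range),
                                    config@de_logfc_range[2])
    }
    if (length(pinned_lfc)) lfc_abs[names(pinned_lfc)] <- abs(pinned_lfc)

    block_of <- stats::setNames(integer(n), symbols)
    block_of[de_up] <- rep(up_blocks, length.out = length(de_up))
    block_of[de_dn] <- rep(dn_blocks, length.out = length(de_dn))

    W <- matrix(0, n, r, dimnames = list(symbols, NULL))
    de_all <- c(de_up, de_dn)
    W[cbind(match(de_all, symbols), block_of[de_all])] <- lfc_abs[de_all]

    # non-exclusive membership with a continuous specificity spectrum: each
    # DE gene moves a random share (up to overlap_frac) of its loading onto
    # a second same-direction block, preserving the planted total log fold
    # change exactly. Genes with a near-zero share are metagene-specific
    # (Kim-Park score near 1); larger shares give intermediate scores, so
    # the screening rule has a realistic upper tail to threshold.
    for (cat in list(list(g = de_up, blocks = up_blocks),
                     list(g = de_dn, blocks = dn_blocks))) {
      if (length(cat$blocks) >= 2L && config@overlap_frac > 0) {
        beta <- stats::runif(length(cat$g), 0, config@overlap_frac)
        for (j in seq_along(cat$g)) {
          gene <- cat$g[j]
          q1 <- block_of[gene]
          q2 <- .resample(setdiff(cat$blocks, q1), 1L)
          tot <- lfc_abs[gene]
          W[gene, q1] <- (1 - beta[j]) * tot
          W[gene, q2] <- beta[j] * tot
        }
      }
    }
    if (length(null_genes)) {
      w0 <- stats::runif(length(null_genes), 0.3, 0.8)
      idx <- match(null_genes, symbols)
      for (i in seq_along(null_genes)) {
        ku <- sample(seq_len(min(2L, length(up_blocks))), 1L)
        kd <- sample(seq_len(min(2L, length(dn_blocks))), 1L)
        qu <- .resample(up_blocks, ku)
        qd <- .resample(dn_blocks, kd)
        W[idx[i], qu] <- w0[i] / ku
        W[idx[i], qd] <- w0[i] / kd
      }
      # argmax assignment, ties to the lowest index
      block_of[null_genes] <- max.col(W[idx, , drop = FALSE],
                                      ties.method = "first")
    }

    # per-metagene activation profiles: baseline + case offset + group-
    # centred sample variation. The variation profiles are orthogonalized
    # across metagenes and scaled inversely to the loading mass of their
    # block, so every planted metagene contributes an equal, well-separated
    # share of the signal variance; this balanced construction is what
    # makes the planted rank cleanly recoverable from the RSS curve.
    b_q <- stats::runif(r, config@baseline_range[1], config@baseline_range[2])
    is_case <- c(rep(FALSE, n1), rep(TRUE, n2))
    hvar <- matrix(0, r, m)
    if (config@sample_effect_sd > 0 && m > 3L) {
      raw <- matrix(stats::rnorm(r * m, 0, 1), r, m)
      raw[, !is_case] <- raw[, !is_case] - rowMeans(raw[, !is_case,
                                                        drop = FALSE])
      raw[, is_case] <- raw[, is_case] - rowMeans(raw[, is_case,
                                                      drop = FALSE])
      k <- min(r, m - 2L)  # group-centred profiles span at most m - 2 dims
      Q <- qr.Q(qr(t(raw)))[, seq_len(k), drop = FALSE]
      col_norm <- sqrt(colSums(W^2))
      target <- config@sample_effect_sd * sqrt(m) * mean(col_norm)
      for (q in seq_len(k)) {
        prof <- Q[, q] * target / col_norm[q]
        # keep the activation profile safely positive (preserves the exact
        # group-centring, hence exact planted log fold changes)
        headroom <- b_q[q] - 1.5
        peak <- max(abs(prof))
        if (peak > headroom) prof <- prof * headroom / peak
        hvar[q, ] <- prof
      }
    }
    H <- b_q + hvar + outer(d_q, as.numeric(is_case))
    H <- pmax(H, 1e-9)

    sample_ids <- c(sprintf("CTRL_%02d", seq_len(n1)),
                    sprintf("CASE_%02d", seq_len(n2)))
    colnames(H) <- sample_ids
    M <- W %*% H

    # probe layer: 1-3 probes per gene with independent noise
    k <- sample(1:3, n, replace = TRUE, prob = config@probe_dist)
    gene_idx <- rep(seq_len(n), k)
    P <- M[gene_idx, , drop = FALSE]
    if (config@noise_sd > 0) {
      P <- P + matrix(stats::rnorm(length(P), 0, config@noise_sd),
                      nrow(P), ncol(P))
    }
    if (config@n_unannotated > 0L) {
      base <- stats::runif(config@n_unannotated, 4, 10)
      D <- matrix(base, config@n_unannotated, m) +
        matrix(stats::rnorm(config@n_unannotated * m, 0,
                            max(config@noise_sd, 0.1)),
               config@n_unannotated, m)
      P <- rbind(P, D)
    }
    P <- pmax(P, 0)
    rownames(P) <- sprintf("%06d_at", 100000L + seq_len(nrow(P)))
    annotated <- seq_along(gene_idx)
    annotation <- stats::setNames(symbols[gene_idx], rownames(P)[annotated])
    groups <- stats::setNames(ifelse(is_case, "case", "control"), sample_ids)

    dataset <- ExpressionDataset(P, groups, annotation)
    S4Vectors::metadata(dataset)$log2_transformed <- FALSE
    signed <- lfc_abs[de_all] * ifelse(de_all %in% de_up, 1, -1)
    truth <- methods::new("GroundTruth",
      de_up = de_up, de_down = de_dn,
      membership = block_of,
      hubs = hubs,
      basisTruth = W,
      coefTruth = H,
      logfc = stats::setNames(as.numeric(signed), de_all),
      seed = config@seed)
    list(dataset = dataset, truth = truth)
  })
}

#' Simulate a scale-free interactome with planted hubs
#'
#' Builds a preferential-attachment (scale-free-ish) undirected simple graph
#' over a sample of the simulated gene symbols, then adds edges so that
#' every planted hub gene reaches at least `network_hub_degree` neighbours.
#' Edges incident to a planted hub carry high confidence scores (>= 0.9,
#' surviving a STRING-style high-confidence filter); other edges carry
#' scores in [0.4, 1).
#'
#' @param config a [SimulationConfig-class].
#' @param truth the matching [GroundTruth-class].
#' @return a `data.frame` with columns `node_a`, `node_b`, `score`.
#' @export
simulateNetwork <- function(config, truth) {
  stopifnot(methods::is(config, "SimulationConfig"),
            methods::is(truth, "GroundTruth"))
  withSeed(config@seed + 1L, {
    symbols <- names(truth@membership)
    n_nodes <- min(config@network_n_nodes, length(symbols))
    others <- setdiff(symbols, truth@hubs)
    nodes <- c(truth@hubs, sample(others, n_nodes - length(truth@hubs)))
    g <- igraph::sample_pa(n_nodes, power = 1, m = 3, directed = FALSE)
    igraph::V(g)$name <- sample(nodes)
    for (hub in truth@hubs) {
      need <- config@network_hub_degree -
        igraph::degree(g, v = hub)
      if (need > 0) {
        nbrs <- names(igraph::neighbors(g, hub))
        cand <- setdiff(nodes, c(hub, nbrs))
        new <- sample(cand, min(need, length(cand)))
        g <- igraph::add_edges(g, rbind(hub, new))
      }
    }
    g <- igraph::simplify(g)
    el <- igraph::as_edgelist(g)
    a <- pmin(el[, 1], el[, 2])
    b <- pmax(el[, 1], el[, 2])
    hub_edge <- a %in% truth@hubs | b %in% truth@hubs
    score <- ifelse(hub_edge,
                    stats::runif(length(a), 0.90, 0.999),
                    stats::runif(length(a), 0.40, 0.999))
    df <- data.frame(node_a = a, node_b = b, score = score,
                     stringsAsFactors = FALSE)
    df <- df[order(df$node_a, df$node_b), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
}

#' Simulate annotation resources with planted positives
#'
#' Generates (i) a gene-set collection in which each planted metagene's DE
#' members form one set (so enrichment must flag it) plus random decoy sets,
#' (ii) a gene-disease association table linking every planted hub to at
#' least two neurological-disorder labels, and (iii) a TF-target table in
#' which each synthetic transcription factor targets planted hub genes.
#'
#' @param config a [SimulationConfig-class].
#' @param truth the matching [GroundTruth-class].
#' @param n_decoy_sets number of random decoy gene sets.
#' @return a list with `gene_sets` ([GeneSetCollection-class]),
#'   `gene_disease` and `tf_targets` (association `data.frame`s).
#' @export
simulateAnnotations <- function(config, truth, n_decoy_sets = 30) {
  stopifnot(methods::is(config, "SimulationConfig"),
            methods::is(truth, "GroundTruth"))
  withSeed(config@seed + 2L, {
    genes <- names(truth@membership)
    de <- c(truth@de_up, truth@de_down)
    cats <- c("KEGG", "BP", "CC", "MF")
    sets <- list(); category <- character()
    for (q in seq_len(ncol(truth@basisTruth))) {
      core <- intersect(de, names(truth@membership)[truth@membership == q])
      if (length(core) >= 2L) {
        nm <- sprintf("PLANTED_METAGENE_%02d", q)
        sets[[nm]] <- core
        category[nm] <- cats[(q - 1L) %% 4L + 1L]
      }
    }
    for (i in seq_len(n_decoy_sets)) {
      nm <- sprintf("RANDOM_SET_%02d", i)
      sets[[nm]] <- sample(genes, sample(10:40, 1L))
      category[nm] <- cats[(i - 1L) %% 4L + 1L]
    }
    collection <- methods::new("GeneSetCollection", sets = sets,
                               category = category,
                               description = category)

    diseases <- c("Alzheimer disease", "cognition disorder",
                  "schizophrenia", "amyotrophic lateral sclerosis")
    gda <- do.call(rbind, lapply(truth@hubs, function(h) {
      dx <- sample(diseases, sample(2:4, 1L))
      data.frame(gene = h, entity = dx,
                 score = stats::runif(length(dx), 0.6, 0.95),
                 stringsAsFactors = FALSE)
    }))
    decoy <- data.frame(
      gene = sample(setdiff(genes, truth@hubs), 40),
      entity = sample(c(diseases, "essential hypertension", "migraine"),
                      40, replace = TRUE),
      score = stats::runif(40, 0.3, 0.9), stringsAsFactors = FALSE)
    gda <- rbind(gda, decoy)

    tfs <- sprintf("TF%02d", 1:8)
    tf <- do.call(rbind, lapply(tfs, function(tf1) {
      targets <- unique(c(
        if (length(truth@hubs)) {
          .resample(truth@hubs, min(length(truth@hubs), sample(2:4, 1L)))
        },
        sample(genes, sample(3:6, 1L))))
      data.frame(gene = targets, entity = tf1,
                 score = stats::runif(length(targets), 0.4, 0.95),
                 stringsAsFactors = FALSE)
    }))
    rownames(gda) <- rownames(tf) <- NULL
    list(gene_sets = collection, gene_disease = gda, tf_targets = tf)
  })
}

#' Simulate a complete two-dataset study on disk
#'
#' Convenience wrapper generating every pipeline input: a primary dataset
#' (with planted DE genes, rank structure and hubs), a second validation
#' dataset that shares the gene universe and whose planted DE genes are
#' disjoint from the primary dataset's except for the planted hub genes
#' (pinned up-regulated in both, emulating shared disease biomarkers), the
#' synthetic interactome, gene sets and association tables. All files are
#' written as tab-separated text under `dir`.
#'
#' @param config primary-dataset [SimulationConfig-class].
#' @param config2 validation-dataset configuration; by default a small
#'   2-vs-2 design with 78 planted up- and 123 planted down-regulated genes
#'   on the same gene universe.
#' @param dir output directory (created if needed).
#' @return a list with `paths` (named file paths), `truth1`, `truth2`,
#'   `shared_hubs`, and the two configurations.
#' @export
simulateStudy <- function(config = simulationConfig(), config2 = NULL,
                          dir = tempfile("study")) {
  if (is.null(config2)) {
    config2 <- simulationConfig(
      n_genes = config@n_genes,
      n_samples_per_group = c(2, 2),
      n_de_up = 78, n_de_down = 123,
      de_logfc_range = config@de_logfc_range,
      r_true = 4,
      noise_sd = config@noise_sd,
      sample_effect_sd = min(config@sample_effect_sd, 0.1),
      baseline_range = config@baseline_range,
      overlap_frac = config@overlap_frac,
      n_unannotated = config@n_unannotated,
      network_n_nodes = config@network_n_nodes,
      network_hub_degree = config@network_hub_degree,
      n_hubs = config@n_hubs,
      seed = config@seed + 1013L)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim1 <- simulateExpression(config)
  net <- simulateNetwork(config, sim1$truth)
  ann <- simulateAnnotations(config, sim1$truth)
  pinned <- withSeed(config@seed + 3L, {
    stats::setNames(
      stats::runif(length(sim1$truth@hubs),
                   mean(config2@de_logfc_range), config2@de_logfc_range[2]),
      sim1$truth@hubs)
  })
  sim2 <- simulateExpression(
    config2,
    gene_symbols = names(sim1$truth@membership),
    pinned_lfc = pinned,
    de_exclude = c(sim1$truth@de_up, sim1$truth@de_down))

  paths <- list(
    expr1 = file.path(dir, "expr1.tsv"),
    groups1 = file.path(dir, "groups1.tsv"),
    annot1 = file.path(dir, "annot1.tsv"),
    expr2 = file.path(dir, "expr2.tsv"),
    groups2 = file.path(dir, "groups2.tsv"),
    annot2 = file.path(dir, "annot2.tsv"),
    gmt = file.path(dir, "gene_sets.gmt"),
    edges = file.path(dir, "interactome.tsv"),
    gda = file.path(dir, "gene_disease.tsv"),
    tf = file.path(dir, "tf_targets.tsv"))
  writeExpression(sim1$dataset, paths$expr1, paths$groups1, paths$annot1)
  writeExpression(sim2$dataset, paths$expr2, paths$groups2, paths$annot2)
  writeGMT(ann$gene_sets, paths$gmt)
  writeEdgeList(net, paths$edges)
  writeAssociation(ann$gene_disease, paths$gda)
  writeAssociation(ann$tf_targets, paths$tf)
  list(paths = paths, truth1 = sim1$truth, truth2 = sim2$truth,
       shared_hubs = sim1$truth@hubs, config = config, config2 = config2)
}
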