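# End-to-end orchestration: DEG selection on both datasets, NMF rank
# selection and metagene extraction on the primary dataset, enrichment,
# network hub ranking, cross-dataset validation and report files.

#' Cross-dataset validation of shared DEGs
#'
#' Intersects the DEG symbol sets of two datasets, reports per-dataset
#' expression, log fold change and p value for every common gene, flags
#' sign consistency (log-fold-change signs agree), and records which common
#' genes are also hubs or metagene members in the first dataset.
#'
#' @param deg1,deg2 selected DEG tables ([selectDEGs()]) of the two
#'   datasets.
#' @param hubs1 optional hub table of dataset 1 ([rankHubs()]).
#' @param metagenes1 optional [MetageneSet-class] of dataset 1.
#' @return a [ValidationReport-class]; empty (with a warning) when the
#'   DEG sets are disjoint.
#' @export
crossValidate <- function(deg1, deg2, hubs1 = NULL, metagenes1 = NULL) {
  common <- sort(intersect(deg1$gene, deg2$gene))
  if (length(common) == 0L) {
    warning("no common DEGs between the two datasets")
    return(methods::new("ValidationReport",
                        table = S4Vectors::DataFrame(
                          gene = character(), expr1 = numeric(),
                          logFC1 = numeric(), p1 = numeric(),
                          expr2 = numeric(), logFC2 = numeric(),
                          p2 = numeric(), sign_consistent = logical(),
                          is_hub1 = logical(), in_metagene1 = logical()),
                        common_genes = character(),
                        hub_overlap = character()))
  }
  i1 <- match(common, deg1$gene)
  i2 <- match(common, deg2$gene)
  hub_genes <- if (is.null(hubs1)) character() else hubs1$gene
  mg_genes <- if (is.null(metagenes1)) character() else {
    memberTable(metagenes1)$gene
  }
  tab <- S4Vectors::DataFrame(
    gene = common,
    expr1 = deg1$mean_expr[i1], logFC1 = deg1$logFC[i1], p1 = deg1$p[i1],
    expr2 = deg2$mean_expr[i2], logFC2 = deg2$logFC[i2], p2 = deg2$p[i2],
    sign_consistent = sign(deg1$logFC[i1]) == sign(deg2$logFC[i2]),
    is_hub1 = common %in% hub_genes,
    in_metagene1 = common %in% mg_genes)
  methods::new("ValidationReport", table = tab, common_genes = common,
               hub_overlap = common[tab$is_hub1 | tab$in_metagene1])
}

.defaultPipelineConfig <- function() {
  list(
    low_expr_quantile = 0.2,
    p_cut = 0.05, lfc_cut = 0.5, use_adjusted = FALSE, moderation = TRUE,
    rank_min = 3L, rank_max = 30L, n_restarts = 10L,
    scan_max_iter = 1500L, scan_tol = 1e-8,
    fit_max_iter = 2000L, fit_tol = 1e-6,
    knee_method = "perpendicular",
    min_score = 0.9, network_order = "first", top_hubs = 10L,
    min_shared = 2L, assoc_min_score = 0, top_members = 15L,
    seed = 1L)
}

.writeTSV <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full metagene-discovery pipeline
#'
#' Executes, in order: read + filter + collapse of the primary dataset,
#' moderated-t DEG selection, NMF target construction, rank scan with
#' knee-point selection, best-of-restarts factorization at the chosen rank,
#' Kim-Park metagene extraction, per-metagene over-representation analysis,
#' interaction-subnetwork construction and hub ranking, DEG selection on
#' the validation dataset, cross-dataset validation, and gene-disease /
#' TF-target bipartite reports on the validated genes. Every stage writes a
#' TSV under `out_dir` and a deterministic JSON manifest records inputs,
#' parameters and headline numbers. All randomness derives from
#' `config$seed`.
#'
#' @param config a named list; required entries are the input paths
#'   `expr1`, `groups1`, `annot1`, `expr2`, `groups2`, `annot2`, `gmt`,
#'   `edges`, `gda`, `tf` and `out_dir`, or alternatively a path to a YAML
#'   file holding them. Threshold/parameter entries default to
#'   raw `p < 0.05`, `|logFC| > 0.5`, low-expression quantile 0.2, rank
#'   grid 3..30 with 10 restarts, interaction score 0.9, top 10 hubs,
#'   `min_shared` 2, seed 1.
#' @return invisibly, a list with the fitted objects (`deg1`, `deg2`,
#'   `curve`, `fit`, `metagenes`, `enrichment`, `network`, `hubs`,
#'   `validation`, `gda_report`, `tf_report`), the `manifest` and the
#'   output `paths`.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(.defaultPipelineConfig(), config)
  need <- c("expr1", "groups1", "annot1", "expr2", "groups2", "annot2",
            "gmt", "edges", "gda", "tf", "out_dir")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("missing config entries: ",
                         paste(miss, collapse = ", "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ds1 <- stage("read_primary", {
    collapseProbes(filterLowExpression(
      readExpression(cfg$expr1, cfg$groups1, cfg$annot1),
      quantile = cfg$low_expr_quantile))
  })
  deg1 <- stage("deg_primary", moderatedT(ds1, moderation = cfg$moderation))
  degs1 <- stage("deg_primary", selectDEGs(deg1, cfg$p_cut, cfg$lfc_cut,
                                           use_adjusted = cfg$use_adjusted))

  V <- stage("build_target", buildTarget(ds1, degs1))
  curve <- stage("select_rank", selectRank(
    V, rank_grid = seq(cfg$rank_min, cfg$rank_max),
    n_restarts = cfg$n_restarts, base_seed = cfg$seed,
    max_iter = cfg$scan_max_iter, tol = cfg$scan_tol,
    method = cfg$knee_method))
  r <- chosenRank(curve)
  fit <- stage("nmf_fit", {
    fits <- lapply(seq_len(cfg$n_restarts), function(i) {
      nmfFit(V, r, seed = cfg$seed + i - 1L,
             max_iter = cfg$fit_max_iter, tol = cfg$fit_tol)
    })
    fits[[which.min(vapply(fits, residualSS, numeric(1)))]]
  })

  mg <- stage("metagenes", {
    sel <- selectMetageneGenes(basisMatrix(fit))
    if (nrow(memberTable(sel)) > 0L) {
      rankMetagenes(sel, top = cfg$top_members)
    } else {
      sel  # an empty screen is reported, not an error
    }
  })

  collection <- stage("enrichment", readGMT(cfg$gmt))
  universe <- rownames(ds1)
  enr <- stage("enrichment", {
    mem <- memberTable(mg)
    kept <- sort(unique(mem$metagene))
    parts <- lapply(kept, function(q) {
      res <- enrichGeneSets(mem$gene[mem$metagene == q], collection,
                            universe)
      if (nrow(res) == 0L) return(NULL)
      res$metagene <- q
      res
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts)) do.call(rbind, parts) else {
      S4Vectors::DataFrame(category = character(), term = character(),
                           k = integer(), n = integer(), K = integer(),
                           N = integer(), percent = numeric(),
                           p = numeric(), fdr = numeric(),
                           genes = character(), metagene = integer())
    }
  })

  net <- stage("network", {
    addCentralities(buildSubnetwork(
      degs1$gene, readEdgeList(cfg$edges),
      min_score = cfg$min_score, order = cfg$network_order))
  })
  hubs <- stage("network", rankHubs(net, k = cfg$top_hubs,
                                    deg_table = deg1, metagenes = mg))

  ds2 <- stage("read_validation", {
    collapseProbes(filterLowExpression(
      readExpression(cfg$expr2, cfg$groups2, cfg$annot2),
      quantile = cfg$low_expr_quantile))
  })
  deg2 <- stage("deg_validation", moderatedT(ds2,
                                             moderation = cfg$moderation))
  degs2 <- stage("deg_validation", selectDEGs(deg2, cfg$p_cut, cfg$lfc_cut,
                                              use_adjusted = cfg$use_adjusted))

  val <- stage("validate", crossValidate(degs1, degs2, hubs1 = hubs,
                                         metagenes1 = mg))
  gda_rep <- stage("gda", bipartiteReport(
    commonGenes(val), readAssociation(cfg$gda),
    min_score = cfg$assoc_min_score, min_shared = cfg$min_shared))
  tf_rep <- stage("tfi", bipartiteReport(
    commonGenes(val), readAssociation(cfg$tf),
    min_score = cfg$assoc_min_score, min_shared = cfg$min_shared,
    rank_by_centrality = TRUE))

  out <- function(f) file.path(cfg$out_dir, f)
  paths <- c(
    deg1 = .writeTSV(degs1, out("deg_primary.tsv")),
    deg2 = .writeTSV(degs2, out("deg_validation.tsv")),
    curve = .writeTSV(data.frame(rank = curve@ranks, rss = curve@rss,
                                 chosen = curve@ranks == r),
                      out("rank_curve.tsv")),
    basis = .writeTSV(data.frame(gene = rownames(basisMatrix(fit)),
                                 basisMatrix(fit), check.names = FALSE),
                      out("basis.tsv")),
    coef = .writeTSV(data.frame(metagene = seq_len(r), coefMatrix(fit),
                                check.names = FALSE),
                     out("coefficients.tsv")),
    metagenes = .writeTSV(memberTable(mg), out("metagenes.tsv")),
    enrichment = .writeTSV(enr, out("enrichment.tsv")),
    nodes = .writeTSV(nodeTable(net), out("network_nodes.tsv")),
    edges = .writeTSV(igraph::as_data_frame(networkGraph(net)),
                      out("network_edges.tsv")),
    hubs = .writeTSV(hubs, out("hubs.tsv")),
    validation = .writeTSV(val@table, out("validation.tsv")),
    gda = .writeTSV(gda_rep, out("gda_report.tsv")),
    tf = .writeTSV(tf_rep, out("tf_report.tsv")))

  input_keys <- setdiff(need, "out_dir")
  manifest <- list(
    parameters = cfg[setdiff(names(cfg), need)],
    inputs = lapply(cfg[input_keys], basename),
    n_genes_analyzed = nrow(ds1),
    n_deg_primary = nrow(degs1),
    n_deg_primary_up = sum(degs1$direction == "up"),
    n_deg_primary_down = sum(degs1$direction == "down"),
    chosen_rank = r,
    rank_grid = range(curve@ranks),
    rss_at_chosen_rank = residualSS(fit),
    n_metagene_members = nrow(memberTable(mg)),
    n_metagenes_kept = length(unique(memberTable(mg)$metagene)),
    n_network_nodes = igraph::vcount(networkGraph(net)),
    n_network_edges = igraph::ecount(networkGraph(net)),
    n_deg_validation = nrow(degs2),
    n_deg_validation_up = sum(degs2$direction == "up"),
    n_deg_validation_down = sum(degs2$direction == "down"),
    n_common_genes = length(commonGenes(val)),
    n_sign_consistent = sum(val@table$sign_consistent),
    n_hub_overlap = length(hubOverlap(val)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(deg1 = degs1, deg2 = degs2, deg_table1 = deg1,
                 deg_table2 = deg2, curve = curve, fit = fit,
                 metagenes = mg, enrichment = enr, network = net,
                 hubs = hubs, validation = val, gda_report = gda_rep,
                 tf_report = tf_rep, manifest = manifest,
                 paths = c(paths, manifest = out("manifest.json"))))
}
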