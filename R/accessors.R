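# Accessors and show methods.

#' @rdname accessors
#' @param x an object of one of the package's S4 classes.
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))
#' @rdname accessors
#' @export
setGeneric("coefMatrix", function(x) standardGeneric("coefMatrix"))
#' @rdname accessors
#' @export
setGeneric("residualSS", function(x) standardGeneric("residualSS"))
#' @rdname accessors
#' @export
setGeneric("chosenRank", function(x) standardGeneric("chosenRank"))
#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
#' @rdname accessors
#' @export
setGeneric("probeAnnotation", function(x) standardGeneric("probeAnnotation"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("setCategories", function(x) standardGeneric("setCategories"))
#' @rdname accessors
#' @export
setGeneric("memberTable", function(x) standardGeneric("memberTable"))
#' @rdname accessors
#' @export
setGeneric("activationLevels", function(x) standardGeneric("activationLevels"))
#' @rdname accessors
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))
#' @rdname accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))
#' @rdname accessors
#' @export
setGeneric("commonGenes", function(x) standardGeneric("commonGenes"))
#' @rdname accessors
#' @export
setGeneric("hubOverlap", function(x) standardGeneric("hubOverlap"))

#' Accessors for MetageneNMF classes
#'
#' Small accessor functions exposing the slots of the package's S4 classes
#' (factor matrices, RSS values, group labels, metagene member tables, graph
#' and node tables, validation results) without direct slot access.
#'
#' @name accessors
#' @return the corresponding slot value.
NULL

#' @rdname accessors
setMethod("basisMatrix", "Factorization", function(x) x@W)
#' @rdname accessors
setMethod("coefMatrix", "Factorization", function(x) x@H)
#' @rdname accessors
setMethod("residualSS", "Factorization", function(x) x@rss)
#' @rdname accessors
setMethod("residualSS", "RankCurve", function(x) {
  stats::setNames(x@rss, x@ranks)
})
#' @rdname accessors
setMethod("chosenRank", "RankCurve", function(x) x@chosen_rank)
#' @rdname accessors
setMethod("basisMatrix", "GroundTruth", function(x) x@basisTruth)
#' @rdname accessors
setMethod("coefMatrix", "GroundTruth", function(x) x@coefTruth)

#' @rdname accessors
setMethod("sampleGroups", "ExpressionDataset", function(x) {
  stats::setNames(as.character(SummarizedExperiment::colData(x)$group),
                  colnames(x))
})
#' @rdname accessors
setMethod("probeAnnotation", "ExpressionDataset", function(x) {
  stats::setNames(
    as.character(SummarizedExperiment::rowData(x)$gene_symbol), rownames(x))
})

#' @rdname accessors
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)
#' @rdname accessors
setMethod("setCategories", "GeneSetCollection", function(x) x@category)

#' @rdname accessors
setMethod("memberTable", "MetageneSet", function(x) x@members)
#' @rdname accessors
setMethod("activationLevels", "MetageneSet", function(x) x@activation)

#' @rdname accessors
setMethod("networkGraph", "InteractionNetwork", function(x) x@graph)
#' @rdname accessors
setMethod("nodeTable", "InteractionNetwork", function(x) x@nodes)

#' @rdname accessors
setMethod("commonGenes", "ValidationReport", function(x) x@common_genes)
#' @rdname accessors
setMethod("hubOverlap", "ValidationReport", function(x) x@hub_overlap)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@n_genes, "genes,",
      paste(object@n_samples_per_group, collapse = " vs "), "samples\n")
  cat("  planted DE:", object@n_de_up, "up /", object@n_de_down, "down,",
      "|logFC| in [", paste(object@de_logfc_range, collapse = ", "), "]\n")
  cat("  planted rank:", object@r_true,
      " noise sd:", object@noise_sd,
      " seed:", object@seed, "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@membership), "genes,",
      length(object@de_up), "up /", length(object@de_down), "down,",
      ncol(object@basisTruth), "planted metagenes,",
      length(object@hubs), "planted hubs\n")
})

setMethod("show", "Factorization", function(object) {
  cat("Factorization: rank", object@r, "on", nrow(object@W), "x",
      ncol(object@H), "target\n")
  cat("  rss:", format(object@rss), " iterations:", object@n_iter,
      " converged:", object@converged, "\n")
})

setMethod("show", "RankCurve", function(object) {
  cat("RankCurve over ranks", min(object@ranks), "..", max(object@ranks),
      "(", length(object@ranks), "points )\n")
  if (!is.na(object@chosen_rank)) {
    cat("  knee-selected rank:", object@chosen_rank, "\n")
  } else cat("  rank not yet selected\n")
})

setMethod("show", "MetageneSet", function(object) {
  kept <- sort(unique(object@members$metagene))
  cat("MetageneSet:", nrow(object@members), "member genes in",
      length(kept), "of", object@n_metagenes, "metagenes\n")
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "sets")
  if (length(object@sets)) {
    cat(" (categories:",
        paste(sort(unique(object@category)), collapse = ", "), ")")
  }
  cat("\n")
})

setMethod("show", "InteractionNetwork", function(object) {
  cat("InteractionNetwork:", igraph::vcount(object@graph), "nodes,",
      igraph::ecount(object@graph), "edges,",
      sum(object@nodes$is_seed), "seeds\n")
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport:", length(object@common_genes),
      "genes DE in both datasets;",
      sum(object@table$sign_consistent), "sign-consistent;",
      length(object@hub_overlap), "hub/metagene overlaps\n")
})
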