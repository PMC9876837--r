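#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The defaults mirror a
#' two-group brain microarray design: 15 control versus 18 case samples
#' (5 vs 6 donors in each of three cell types), 218 up- and 780 down-regulated
#' planted genes, a planted factorization rank of 10 and log2-scale Gaussian
#' noise.
#'
#' @slot n_genes number of distinct gene symbols.
#' @slot probe_dist probabilities of a gene being measured by 1, 2 or 3
#'   probes.
#' @slot n_samples_per_group control and case sample counts.
#' @slot n_de_up,n_de_down numbers of planted up-/down-regulated genes.
#' @slot de_logfc_range interval (log2 scale) the planted absolute log fold
#'   changes are drawn from.
#' @slot r_true planted factorization rank (number of planted metagenes).
#' @slot noise_sd standard deviation of the additive probe-level noise
#'   (log2 units).
#' @slot sample_effect_sd standard deviation of the per-sample variation of
#'   the metagene activation profiles (log2 units).
#' @slot baseline_range interval the per-metagene baseline activations are
#'   drawn from (log2 units).
#' @slot overlap_frac maximum share of a planted DE gene's loading carried
#'   by a second metagene of the same direction.
#' @slot n_unannotated number of decoy probes without a gene-symbol
#'   annotation.
#' @slot network_n_nodes number of nodes of the synthetic interactome.
#' @slot network_hub_degree guaranteed minimum degree of planted hub genes.
#' @slot n_hubs number of planted hub genes (drawn from the up-regulated
#'   set, with effect sizes in the upper part of `de_logfc_range`).
#' @slot seed integer seed; all generator randomness derives from it.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(
    n_genes = "integer",
    probe_dist = "numeric",
    n_samples_per_group = "integer",
    n_de_up = "integer",
    n_de_down = "integer",
    de_logfc_range = "numeric",
    r_true = "integer",
    noise_sd = "numeric",
    sample_effect_sd = "numeric",
    baseline_range = "numeric",
    overlap_frac = "numeric",
    n_unannotated = "integer",
    network_n_nodes = "integer",
    network_hub_degree = "integer",
    n_hubs = "integer",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@n_genes < 1L) msg <- c(msg, "n_genes must be positive")
  if (object@n_de_up < 1L || object@n_de_down < 1L) {
    msg <- c(msg, "n_de_up and n_de_down must be positive")
  }
  if (object@n_de_up + object@n_de_down > object@n_genes) {
    msg <- c(msg, "n_de_up + n_de_down must not exceed n_genes")
  }
  if (object@r_true < 2L) msg <- c(msg, "r_true must be >= 2")
  if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be nonnegative")
  if (object@sample_effect_sd < 0) {
    msg <- c(msg, "sample_effect_sd must be nonnegative")
  }
  if (any(object@n_samples_per_group < 1L)) {
    msg <- c(msg, "sample counts must be positive")
  }
  if (length(object@probe_dist) != 3L || any(object@probe_dist < 0) ||
      abs(sum(object@probe_dist) - 1) > 1e-8) {
    msg <- c(msg, "probe_dist must be 3 probabilities summing to 1")
  }
  if (object@overlap_frac < 0 || object@overlap_frac > 0.5) {
    msg <- c(msg, "overlap_frac must be in [0, 0.5]")
  }
  if (object@network_n_nodes < object@n_hubs + 2L) {
    msg <- c(msg, "network_n_nodes too small for the planted hubs")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated dataset
#'
#' Planted structure recorded by [simulateExpression()]: the up-/down-
#' regulated gene sets, the gene-to-metagene membership map, the planted hub
#' genes, and the exact planted factors so that the noise-free signal matrix
#' can be reconstructed as `basisTruth %*% coefTruth`.
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
  slots = c(
    de_up = "character",
    de_down = "character",
    membership = "integer",
    hubs = "character",
    basisTruth = "matrix",
    coefTruth = "matrix",
    logfc = "numeric",
    seed = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  genes <- names(object@membership)
  msg <- character()
  if (!all(object@de_up %in% genes) || !all(object@de_down %in% genes)) {
    msg <- c(msg, "DE gene sets must be subsets of the generated genes")
  }
  if (!all(object@hubs %in% genes)) {
    msg <- c(msg, "hub genes must be generated gene symbols")
  }
  if (length(intersect(object@de_up, object@de_down))) {
    msg <- c(msg, "a gene cannot be both up- and down-regulated")
  }
  if (length(msg)) msg else TRUE
})

#' Two-group expression dataset
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a log2 intensity
#' matrix (probes or genes in rows, samples in columns), a `group` column in
#' `colData` with levels `control`/`case`, and a `gene_symbol` column in
#' `rowData` (`NA` for unannotated probes).
#'
#' @exportClass ExpressionDataset
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  if (length(SummarizedExperiment::assays(object)) < 1L) {
    return("an assay matrix is required")
  }
  m <- SummarizedExperiment::assay(object)
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    msg <- c(msg, "row (probe/gene) identifiers must be unique")
  }
  if (is.null(colnames(m)) || anyDuplicated(colnames(m))) {
    msg <- c(msg, "sample identifiers must be unique")
  }
  if (anyNA(m)) msg <- c(msg, "the expression matrix must not contain NA")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else if (!all(cd$group %in% c("control", "case"))) {
    msg <- c(msg, "groups must be 'control' or 'case'")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!"gene_symbol" %in% colnames(rd)) {
    msg <- c(msg, "rowData must contain a 'gene_symbol' column")
  }
  if (length(msg)) msg else TRUE
})

#' Nonnegative matrix factorization result
#'
#' Factors of `V ~ W %*% H` fitted by multiplicative updates for the
#' Frobenius objective, together with the residual sum of squares
#' `||V - WH||_F^2` and its per-iteration trace (non-increasing by
#' construction).
#'
#' @exportClass Factorization
setClass("Factorization",
  slots = c(
    W = "matrix",
    H = "matrix",
    r = "integer",
    rss = "numeric",
    rss_trace = "numeric",
    n_iter = "integer",
    seed = "integer",
    converged = "logical"
  )
)

setValidity("Factorization", function(object) {
  msg <- character()
  if (any(object@W < 0) || any(object@H < 0)) {
    msg <- c(msg, "W and H must be nonnegative")
  }
  if (ncol(object@W) != object@r || nrow(object@H) != object@r) {
    msg <- c(msg, "inner dimensions must equal the rank")
  }
  if (object@rss < 0) msg <- c(msg, "rss must be nonnegative")
  if (length(object@rss_trace) > 1L) {
    inc <- diff(object@rss_trace)
    if (any(inc > 1e-8 * max(object@rss_trace[1], 1))) {
      msg <- c(msg, "rss trace must be non-increasing")
    }
  }
  if (length(msg)) msg else TRUE
})

#' RSS-versus-rank curve
#'
#' Best-of-restarts residual sum of squares per candidate rank, with the
#' knee-selected rank once [uikKnee()]/[selectRank()] has run.
#'
#' @exportClass RankCurve
setClass("RankCurve",
  slots = c(
    ranks = "integer",
    rss = "numeric",
    chosen_rank = "integer",
    n_restarts = "integer"
  )
)

setValidity("RankCurve", function(object) {
  msg <- character()
  if (length(object@ranks) != length(object@rss)) {
    msg <- c(msg, "ranks and rss must have equal length")
  }
  if (length(object@ranks) < 2L) msg <- c(msg, "at least 2 ranks required")
  if (any(diff(object@ranks) <= 0L)) {
    msg <- c(msg, "ranks must be strictly increasing")
  }
  if (!is.na(object@chosen_rank) &&
      !(object@chosen_rank %in% object@ranks)) {
    msg <- c(msg, "chosen_rank must be one of the scanned ranks")
  }
  if (length(msg)) msg else TRUE
})

#' Metagene membership set
#'
#' Genes passing the Kim-Park screening rule, their hard metagene
#' assignment (argmax of the basis row), row-normalized contributions and
#' entropy scores, plus per-metagene activation (sum of member loadings) and
#' the activation-descending metagene order.
#'
#' @exportClass MetageneSet
setClass("MetageneSet",
  slots = c(
    members = "DataFrame",
    activation = "numeric",
    metagene_order = "integer",
    n_metagenes = "integer"
  )
)

setValidity("MetageneSet", function(object) {
  need <- c("gene", "metagene", "loading", "contribution", "score")
  if (!all(need %in% colnames(object@members))) {
    return(paste("members must have columns:", paste(need, collapse = ", ")))
  }
  ct <- object@members$contribution
  if (length(ct) && (any(ct < -1e-9) || any(ct > 1 + 1e-9))) {
    return("contributions must lie in [0, 1]")
  }
  TRUE
})

#' Gene-set collection
#'
#' Named gene sets (GMT dialect) with a per-set category tag
#' (e.g. KEGG/BP/CC/MF), carried in the GMT description field.
#'
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
  slots = c(
    sets = "list",
    category = "character",
    description = "character"
  )
)

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  nm <- names(object@sets)
  if (length(object@sets)) {
    if (is.null(nm) || anyDuplicated(nm)) {
      msg <- c(msg, "set names must be unique")
    }
    if (any(lengths(object@sets) == 0L)) {
      msg <- c(msg, "sets must have at least one member")
    }
    if (!identical(names(object@category), nm) ||
        !identical(names(object@description), nm)) {
      msg <- c(msg, "category/description must be named like the sets")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Interaction network
#'
#' An undirected simple graph (igraph) together with a node table carrying
#' the seed flag and, once computed, degree and unnormalized betweenness.
#'
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
  slots = c(
    graph = "ANY",
    nodes = "DataFrame"
  )
)

setValidity("InteractionNetwork", function(object) {
  if (!igraph::is_igraph(object@graph)) return("graph must be an igraph")
  if (!igraph::is_simple(object@graph)) {
    return("graph must be simple (no loops or multi-edges)")
  }
  if (nrow(object@nodes) != igraph::vcount(object@graph)) {
    return("node table must match the graph vertices")
  }
  TRUE
})

#' Cross-dataset validation report
#'
#' Genes differentially expressed in both datasets, with per-dataset
#' expression, log fold change and p-value, a sign-consistency flag, and the
#' subset that are also hubs or metagene members in the first dataset.
#'
#' @exportClass ValidationReport
setClass("ValidationReport",
  slots = c(
    table = "DataFrame",
    common_genes = "character",
    hub_overlap = "character"
  )
)

setValidity("ValidationReport", function(object) {
  if (!setequal(object@common_genes, object@table$gene)) {
    return("common_genes must equal the genes of the report table")
  }
  if (!all(object@hub_overlap %in% object@common_genes)) {
    return("hub_overlap must be a subset of common_genes")
  }
  TRUE
})
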