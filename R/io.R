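# Readers and writers for the plain-text table formats the pipeline touches:
# expression matrix TSV, sample-group TSV, probe-annotation TSV, GMT gene
# sets, interaction edge lists and gene-entity association tables. All are
# UTF-8 tab-separated with '#' comment lines.

#' Construct an ExpressionDataset
#'
#' @param exprs numeric matrix of log2 intensities, probes/genes in rows and
#'   samples in columns, with unique dimnames.
#' @param groups named character vector (or 2-column data.frame
#'   `sample, group`) assigning every sample to `control` or `case`.
#' @param annotation optional named character vector (or 2-column data.frame
#'   `probe_id, gene_symbol`) mapping probes to gene symbols; probes without
#'   an entry are kept and flagged unannotated (`NA` symbol).
#' @return an [ExpressionDataset-class].
#' @export
ExpressionDataset <- function(exprs, groups, annotation = NULL) {
  exprs <- as.matrix(exprs)
  if (is.null(rownames(exprs)) || is.null(colnames(exprs))) {
    stop("expression matrix needs probe and sample names")
  }
  if (anyDuplicated(rownames(exprs))) {
    stop("duplicate probe identifiers: ",
         paste(unique(rownames(exprs)[duplicated(rownames(exprs))])[1:3],
               collapse = ", "))
  }
  if (anyDuplicated(colnames(exprs))) {
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(exprs)[duplicated(colnames(exprs))])[1:3],
               collapse = ", "))
  }
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups[[2]]),
                              as.character(groups[[1]]))
  }
  missing <- setdiff(colnames(exprs), names(groups))
  if (length(missing)) {
    stop("samples without a group assignment: ",
         paste(missing, collapse = ", "))
  }
  groups <- groups[colnames(exprs)]
  if (!all(groups %in% c("control", "case"))) {
    stop("group labels must be 'control' or 'case'")
  }
  if (is.data.frame(annotation)) {
    annotation <- stats::setNames(as.character(annotation[[2]]),
                                  as.character(annotation[[1]]))
  }
  symbols <- rep(NA_character_, nrow(exprs))
  if (!is.null(annotation)) {
    hit <- match(rownames(exprs), names(annotation))
    symbols <- trimws(as.character(annotation[hit]))
    symbols[!nzchar(symbols) | is.na(symbols)] <- NA_character_
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs),
    colData = S4Vectors::DataFrame(group = unname(groups),
                                   row.names = colnames(exprs)),
    rowData = S4Vectors::DataFrame(gene_symbol = symbols,
                                   row.names = rownames(exprs))
  )
  methods::new("ExpressionDataset", se)
}

.readLinesNoComment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read an expression dataset from TSV files
#'
#' Reads a probes-by-samples matrix (first column = probe ids, header row =
#' sample ids), a sample-group table and an optional probe-to-symbol
#' annotation table. If the matrix maximum exceeds 50 the values are taken to
#' be linear-scale intensities and are log2 transformed (values below 1 are
#' clipped to 1 first); the transform is recorded in
#' `metadata(x)$log2_transformed`.
#'
#' @param matrix_path,groups_path,annotation_path file paths;
#'   `annotation_path` may be `NULL`.
#' @return an [ExpressionDataset-class].
#' @export
readExpression <- function(matrix_path, groups_path, annotation_path = NULL) {
  tab <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyNA(m)) stop("missing entries in the expression matrix")
  transformed <- FALSE
  if (max(m) > 50) {
    m <- log2(pmax(m, 1))
    transformed <- TRUE
    .msg("matrix maximum > 50: applied log2 transform")
  }
  groups <- utils::read.delim(groups_path, header = TRUE, sep = "\t",
                              comment.char = "#", stringsAsFactors = FALSE)
  annot <- NULL
  if (!is.null(annotation_path)) {
    annot <- utils::read.delim(annotation_path, header = TRUE, sep = "\t",
                               comment.char = "#", stringsAsFactors = FALSE)
    if (anyDuplicated(annot[[1]])) {
      stop("duplicate probe identifiers in the annotation table")
    }
  }
  x <- ExpressionDataset(m, groups, annot)
  S4Vectors::metadata(x)$log2_transformed <- transformed
  n_unannot <- sum(is.na(SummarizedExperiment::rowData(x)$gene_symbol))
  if (n_unannot > 0) .msg("%d probes without annotation (kept)", n_unannot)
  x
}

#' Write an expression dataset to TSV files
#'
#' Inverse of [readExpression()]: writes the matrix, the group table and the
#' annotation table so that reading them back reproduces the dataset.
#'
#' @param x an [ExpressionDataset-class].
#' @param matrix_path,groups_path,annotation_path output file paths;
#'   `annotation_path` may be `NULL` to skip.
#' @return invisibly, the matrix path.
#' @export
writeExpression <- function(x, matrix_path, groups_path,
                            annotation_path = NULL) {
  m <- SummarizedExperiment::assay(x)
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gr <- data.frame(sample = colnames(m), group = unname(sampleGroups(x)),
                   stringsAsFactors = FALSE)
  utils::write.table(gr, groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(annotation_path)) {
    ann <- probeAnnotation(x)
    ann <- ann[!is.na(ann)]
    utils::write.table(
      data.frame(probe_id = names(ann), gene_symbol = unname(ann),
                 stringsAsFactors = FALSE),
      annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(matrix_path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, `name<TAB>description<TAB>gene...`.
#' The description field is used as the set's category tag (KEGG/BP/CC/MF in
#' the bundled generator). Member symbols are trimmed and compared
#' case-sensitively.
#'
#' @param path GMT file path.
#' @return a [GeneSetCollection-class].
#' @export
readGMT <- function(path) {
  got <- .readLinesNoComment(path)
  if (length(got$lines) == 0L) {
    warning("empty GMT file: ", path)
    return(methods::new("GeneSetCollection", sets = list(),
                        category = character(), description = character()))
  }
  fields <- strsplit(got$lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop(sprintf("malformed GMT line %d in %s (need name, description, >=1 gene)",
                 got$lineno[bad[1]], path))
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set names in ", path)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(trimws(f[-(1:2)])))
  names(sets) <- nm
  methods::new("GeneSetCollection", sets = sets,
               category = stats::setNames(desc, nm),
               description = stats::setNames(desc, nm))
}

#' Write a GMT gene-set file
#'
#' @param collection a [GeneSetCollection-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeGMT <- function(collection, path) {
  nm <- names(geneSets(collection))
  lines <- vapply(nm, function(s) {
    paste(c(s, collection@description[[s]], geneSets(collection)[[s]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an interaction edge list
#'
#' Tab-separated `node_a<TAB>node_b<TAB>score` with a header line. Scores
#' must be in `[0, 1]`. Self-loops are dropped; duplicate edges (treating
#' `(a,b)` and `(b,a)` as identical) are collapsed keeping the highest score.
#'
#' @param path edge-list file path.
#' @return a `data.frame` with columns `node_a`, `node_b`, `score`.
#' @export
readEdgeList <- function(path) {
  got <- .readLinesNoComment(path)
  if (length(got$lines) <= 1L) {
    warning("empty edge list: ", path)
    return(data.frame(node_a = character(), node_b = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  body <- got$lines[-1L]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad)) {
    stop(sprintf("malformed edge-list line %d in %s (need 3 fields)",
                 got$lineno[-1L][bad[1]], path))
  }
  a <- trimws(vapply(fields, `[[`, "", 1L))
  b <- trimws(vapply(fields, `[[`, "", 2L))
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(s) | s < 0 | s > 1)
  if (length(bad)) {
    stop(sprintf("malformed edge-list line %d in %s (score outside [0,1])",
                 got$lineno[-1L][bad[1]], path))
  }
  keep <- a != b
  if (any(!keep)) warning(sum(!keep), " self-loops dropped")
  a2 <- pmin(a[keep], b[keep])
  b2 <- pmax(a[keep], b[keep])
  df <- data.frame(node_a = a2, node_b = b2, score = s[keep],
                   stringsAsFactors = FALSE)
  df <- df[order(df$node_a, df$node_b, -df$score), , drop = FALSE]
  df <- df[!duplicated(df[, c("node_a", "node_b")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write an interaction edge list
#'
#' @param edges data.frame with columns `node_a`, `node_b`, `score`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeEdgeList <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene-entity association table
#'
#' Tab-separated `gene<TAB>entity<TAB>score` with a header line, used for
#' gene-disease and TF-target tables.
#'
#' @param path association-table file path.
#' @return a `data.frame` with columns `gene`, `entity`, `score`.
#' @export
readAssociation <- function(path) {
  got <- .readLinesNoComment(path)
  if (length(got$lines) <= 1L) {
    warning("empty association table: ", path)
    return(data.frame(gene = character(), entity = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  body <- got$lines[-1L]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad)) {
    stop(sprintf("malformed association line %d in %s (need 3 fields)",
                 got$lineno[-1L][bad[1]], path))
  }
  data.frame(gene = trimws(vapply(fields, `[[`, "", 1L)),
             entity = trimws(vapply(fields, `[[`, "", 2L)),
             score = as.numeric(vapply(fields, `[[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Write a gene-entity association table
#'
#' @param assoc data.frame with columns `gene`, `entity`, `score`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeAssociation <- function(assoc, path) {
  utils::write.table(assoc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
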