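# Small constructors shared across test files.

toyDataset <- function(mat, groups = NULL, annotation = NULL) {
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("p%02d", seq_len(nrow(mat)))
  }
  if (is.null(colnames(mat))) {
    colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  }
  if (is.null(groups)) {
    half <- floor(ncol(mat) / 2)
    groups <- stats::setNames(
      c(rep("control", half), rep("case", ncol(mat) - half)), colnames(mat))
  }
  if (is.null(annotation)) {
    annotation <- stats::setNames(rownames(mat), rownames(mat))
  }
  ExpressionDataset(mat, groups, annotation)
}

# two-group matrix with genes in rows: control then case columns
nullMatrix <- function(n_genes, n1, n2, sd = 1, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (n1 + n2), mean = 8, sd = sd), n_genes)
  rownames(m) <- sprintf("G%04d", seq_len(n_genes))
  colnames(m) <- c(sprintf("C%02d", seq_len(n1)), sprintf("T%02d", seq_len(n2)))
  m
}

nullDataset <- function(n_genes, n1, n2, sd = 1, seed = 1) {
  m <- nullMatrix(n_genes, n1, n2, sd, seed)
  toyDataset(m, stats::setNames(c(rep("control", n1), rep("case", n2)),
                                colnames(m)))
}
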