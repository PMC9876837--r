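test_that("low-expression filter removes probes below the median quantile", {
  m <- matrix(rep(1:10, each = 4), nrow = 10, byrow = TRUE,
              dimnames = list(paste0("p", 1:10), paste0("s", 1:4)))
  ds <- toyDataset(m)
  expect_equal(nrow(suppressMessages(filterLowExpression(ds, 0))), 10L)
  filtered <- suppressMessages(filterLowExpression(ds, 0.25))
  meds <- apply(m, 1, median)
  cut <- quantile(meds, 0.25, names = FALSE)
  expect_equal(nrow(filtered), sum(meds >= cut))
  # ties at the cutoff retained: constant matrix loses nothing
  const <- toyDataset(matrix(5, 6, 4))
  expect_equal(nrow(suppressMessages(filterLowExpression(const, 0.5))), 6L)
  expect_error(filterLowExpression(ds, 1), "quantile")
})

test_that("probe collapsing averages duplicate symbols", {
  m <- matrix(c(1, 3, 3, 5, 7, 7), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("p", 1:3), c("s1", "s2")))
  ds <- toyDataset(m, groups = c(s1 = "control", s2 = "case"),
                   annotation = c(p1 = "G1", p2 = "G1", p3 = "G2"))
  cd <- suppressMessages(collapseProbes(ds))
  expect_equal(SummarizedExperiment::assay(cd)["G1", ],
               c(s1 = 2, s2 = 4))
  expect_equal(SummarizedExperiment::assay(cd)["G2", ],
               c(s1 = 7, s2 = 7))
  # three probes equal the brute-force mean; unannotated probes dropped
  m2 <- matrix(runif(12, 4, 8), 4,
               dimnames = list(paste0("p", 1:4), paste0("s", 1:3)))
  ds2 <- toyDataset(m2, groups = stats::setNames(
    c("control", "control", "case"), colnames(m2)),
    annotation = c(p1 = "G1", p2 = "G1", p3 = "G1"))
  cd2 <- suppressMessages(collapseProbes(ds2))
  expect_equal(nrow(cd2), 1L)
  expect_equal(unname(SummarizedExperiment::assay(cd2)["G1", ]),
               unname(colMeans(m2[1:3, ])))
})

test_that("ordinary pooled t matches the hand-computed and t.test oracle", {
  m <- rbind(G1 = c(1, 2, 3, 4, 5, 6))
  colnames(m) <- paste0("s", 1:6)
  ds <- toyDataset(m, groups = stats::setNames(
    c(rep("control", 3), rep("case", 3)), colnames(m)))
  tab <- moderatedT(ds, moderation = FALSE)
  expect_equal(tab$logFC, 3)
  expect_equal(tab$t, 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tab$t, 3.6742, tolerance = 1e-4)

  # random small matrices against stats::t.test
  set.seed(42)
  for (i in 1:10) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    ds2 <- nullDataset(20, n1, n2, sd = runif(1, 0.5, 2), seed = i)
    tab2 <- moderatedT(ds2, moderation = FALSE)
    mat <- SummarizedExperiment::assay(ds2)
    for (g in sample(rownames(mat), 5)) {
      tt <- t.test(mat[g, 1:n1], mat[g, n1 + seq_len(n2)],
                   var.equal = TRUE)
      row <- tab2[tab2$gene == g, ]
      expect_equal(row$t, -unname(tt$statistic), tolerance = 1e-10)
      expect_equal(row$p, tt$p.value, tolerance = 1e-10)
    }
  }
})

test_that("a gene with identical group values gets logFC 0, t 0, p 1", {
  m <- rbind(G1 = c(5, 5, 5, 5, 5, 5), G2 = c(1, 2, 3, 6, 7, 9))
  colnames(m) <- paste0("s", 1:6)
  ds <- toyDataset(m, groups = stats::setNames(
    c(rep("control", 3), rep("case", 3)), colnames(m)))
  tab <- suppressWarnings(moderatedT(ds))
  row <- tab[tab$gene == "G1", ]
  expect_equal(row$logFC, 0)
  expect_equal(row$t, 0)
  expect_equal(row$p, 1)
})

test_that("variance shrinkage matches limma's moment-matched prior", {
  skip_if_not_installed("limma")
  set.seed(7)
  n1 <- 4; n2 <- 5
  mat <- nullMatrix(300, n1, n2, sd = 1, seed = 99)
  # heterogeneous gene variances so the prior df is finite
  mat <- mat * exp(rnorm(300, 0, 0.5))
  ds <- toyDataset(mat, stats::setNames(
    c(rep("control", n1), rep("case", n2)), colnames(mat)))
  tab <- moderatedT(ds)
  md <- S4Vectors::metadata(tab)

  s2 <- apply(mat, 1, function(x) {
    (sum((x[1:n1] - mean(x[1:n1]))^2) +
       sum((x[-(1:n1)] - mean(x[-(1:n1)]))^2)) / (n1 + n2 - 2)
  })
  sq <- limma::squeezeVar(s2, df = n1 + n2 - 2)
  expect_equal(md$df_prior, sq$df.prior, tolerance = 1e-6)
  expect_equal(md$var_prior, sq$var.prior, tolerance = 1e-6)

  # full moderated t agrees with limma's eBayes pipeline
  design <- cbind(1, c(rep(0, n1), rep(1, n2)))
  fit <- limma::eBayes(limma::lmFit(mat, design))
  expect_equal(unname(tab$t[match(rownames(mat), tab$gene)]),
               unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(unname(tab$p[match(rownames(mat), tab$gene)]),
               unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("in the strong-shrinkage limit all variances equal the prior", {
  # near-identical gene variances push the prior df towards infinity
  ds <- nullDataset(500, 4, 4, sd = 1, seed = 3)
  tab <- moderatedT(ds)
  md <- S4Vectors::metadata(tab)
  expect_true(!is.finite(md$df_prior) || md$df_prior > 50)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.3), 0.3)
  expect_equal(bhAdjust(c(0.005, 0.1)), c(0.01, 0.1))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(bhAdjust(p), bhOracle(p))
  }
})

test_that("DEG selection applies strict thresholds", {
  tab <- S4Vectors::DataFrame(
    gene = paste0("G", 1:6),
    logFC = c(0.6, 0.5, -0.8, 1.2, -0.4, 0.51),
    t = rnorm(6), p = c(0.04, 0.04, 0.5, 0.01, 0.001, 0.049),
    p_adj = rep(0.2, 6),
    direction = c("up", "up", "down", "up", "down", "up"),
    mean_expr = rep(8, 6))
  sel <- suppressMessages(selectDEGs(tab, 0.05, 0.5))
  # strict: p = 0.04 & logFC 0.6 kept; logFC exactly 0.5 dropped;
  # brute-force count
  expect_setequal(sel$gene, tab$gene[tab$p < 0.05 & abs(tab$logFC) > 0.5])
  expect_equal(nrow(sel), 3L)
  expect_true("G1" %in% sel$gene)
  expect_false("G2" %in% sel$gene)
  # p_cut 1, lfc_cut 0 keeps all genes with nonzero logFC
  sel2 <- suppressMessages(selectDEGs(tab, 1, 0))
  expect_equal(nrow(sel2), 6L)
  expect_warning(selectDEGs(tab, 0.0001, 2), "no genes")
  # adjusted filter uses p_adj
  sel3 <- suppressWarnings(selectDEGs(tab, 0.05, 0.5, use_adjusted = TRUE))
  expect_equal(nrow(sel3), 0L)
})

test_that("DEG tables keep BH monotonicity and direction invariants", {
  ds <- nullDataset(200, 4, 5, seed = 21)
  tab <- moderatedT(ds)
  expect_true(all(tab$p_adj >= tab$p))
  expect_true(all((tab$direction == "up") == (tab$logFC > 0)))
  expect_false(is.unsorted(tab$p))
})
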