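test_that("configurations are validated", {
  expect_error(simulationConfig(n_de_up = 0), ">= 1")
  expect_error(simulationConfig(n_genes = 100, n_de_up = 80, n_de_down = 40),
               "exceed")
  expect_error(simulationConfig(r_true = 1), ">= 2")
  expect_error(simulationConfig(noise_sd = -1), "nonnegative")
  # planted rank cannot exceed the data dimensions
  cfg <- simulationConfig(n_genes = 100, n_de_up = 20, n_de_down = 20,
                          r_true = 9, n_samples_per_group = c(4, 4))
  expect_error(simulateExpression(cfg), "min\\(n_genes, total samples\\)")
})

test_that("the noise-free signal equals the planted factorization exactly", {
  cfg <- simulationConfig(n_genes = 200, n_de_up = 40, n_de_down = 40,
                          r_true = 3, n_samples_per_group = c(5, 6),
                          noise_sd = 0, seed = 4)
  sim <- simulateExpression(cfg)
  cd <- suppressMessages(collapseProbes(sim$dataset))
  WH <- basisMatrix(sim$truth) %*% coefMatrix(sim$truth)
  expect_equal(SummarizedExperiment::assay(cd)[rownames(WH), ], WH,
               tolerance = 1e-12)
  # a rank-3 reconstruction from the planted factors leaves zero residual
  expect_lt(sum((WH - basisMatrix(sim$truth) %*%
                   coefMatrix(sim$truth))^2), 1e-20)
  expect_true(all(SummarizedExperiment::assay(sim$dataset) >= 0))
  expect_true(all(basisMatrix(sim$truth) >= 0))
  expect_true(all(coefMatrix(sim$truth) >= 0))
})

test_that("planted group differences are exact and null genes are flat", {
  cfg <- simulationConfig(n_genes = 200, n_de_up = 40, n_de_down = 40,
                          r_true = 4, n_samples_per_group = c(5, 6),
                          noise_sd = 0, seed = 12)
  sim <- simulateExpression(cfg)
  tr <- sim$truth
  WH <- basisMatrix(tr) %*% coefMatrix(tr)
  grp <- rep(c(FALSE, TRUE), c(5, 6))
  lfc <- rowMeans(WH[, grp]) - rowMeans(WH[, !grp])
  expect_equal(lfc[names(tr@logfc)], tr@logfc, tolerance = 1e-10)
  nulls <- setdiff(names(tr@membership), names(tr@logfc))
  expect_lt(max(abs(lfc[nulls])), 1e-10)
  expect_true(all(abs(tr@logfc) >= cfg@de_logfc_range[1] - 1e-12))
  expect_true(all(abs(tr@logfc) <= cfg@de_logfc_range[2] + 1e-12))
  expect_true(all(tr@logfc[tr@de_up] > 0))
  expect_true(all(tr@logfc[tr@de_down] < 0))
})

test_that("ground truth reports the requested DE split and is deterministic", {
  cfg <- simulationConfig(n_genes = 1500, n_de_up = 218, n_de_down = 780,
                          seed = 2)
  sim <- simulateExpression(cfg)
  expect_length(sim$truth@de_up, 218L)
  expect_length(sim$truth@de_down, 780L)
  sim2 <- simulateExpression(cfg)
  expect_identical(SummarizedExperiment::assay(sim$dataset),
                   SummarizedExperiment::assay(sim2$dataset))
  expect_identical(sim$truth@logfc, sim2$truth@logfc)
  # duplicate probes share a symbol, with distinct probe ids
  ann <- probeAnnotation(sim$dataset)
  expect_gt(sum(duplicated(ann[!is.na(ann)])), 0L)
  expect_false(anyDuplicated(names(ann)) > 0)
})

test_that("annotation resources contain the planted positive controls", {
  cfg <- simulationConfig(n_genes = 300, n_de_up = 60, n_de_down = 60,
                          r_true = 4, n_samples_per_group = c(4, 4),
                          network_n_nodes = 150, n_hubs = 4, seed = 6)
  sim <- simulateExpression(cfg)
  ann <- simulateAnnotations(cfg, sim$truth)
  sets <- geneSets(ann$gene_sets)
  planted <- grep("PLANTED_METAGENE", names(sets), value = TRUE)
  expect_gte(length(planted), 2L)
  de <- c(sim$truth@de_up, sim$truth@de_down)
  for (nm in planted) {
    q <- as.integer(sub("PLANTED_METAGENE_", "", nm))
    core <- intersect(de,
                      names(sim$truth@membership)[sim$truth@membership == q])
    expect_setequal(sets[[nm]], core)
  }
  # genes absent from the truth appear in no positive-control set
  expect_true(all(unlist(sets[planted]) %in% names(sim$truth@membership)))
  # every planted hub is linked to at least two disease labels
  gda <- ann$gene_disease
  for (h in sim$truth@hubs) {
    expect_gte(length(unique(gda$entity[gda$gene == h])), 2L)
  }
  # at least five TFs target hub genes
  tf <- ann$tf_targets
  expect_gte(length(unique(tf$entity[tf$gene %in% sim$truth@hubs])), 5L)
  # deterministic regeneration
  ann2 <- simulateAnnotations(cfg, sim$truth)
  expect_identical(geneSets(ann$gene_sets), geneSets(ann2$gene_sets))
  expect_identical(ann$gene_disease, ann2$gene_disease)
})

test_that("study files round-trip bit-identically through the readers", {
  cfg <- simulationConfig(n_genes = 120, n_de_up = 20, n_de_down = 25,
                          r_true = 3, n_samples_per_group = c(4, 4),
                          network_n_nodes = 80, network_hub_degree = 10,
                          n_hubs = 3, seed = 14)
  cfg2 <- simulationConfig(n_genes = 120, n_de_up = 10, n_de_down = 12,
                           r_true = 3, n_samples_per_group = c(2, 2),
                           network_n_nodes = 80, network_hub_degree = 10,
                           n_hubs = 3, seed = 15)
  td <- withr::local_tempdir()
  study <- suppressMessages(simulateStudy(cfg, cfg2, dir = td))
  ds1 <- suppressMessages(readExpression(study$paths$expr1,
                                         study$paths$groups1,
                                         study$paths$annot1))
  sim1 <- simulateExpression(cfg)
  expect_equal(SummarizedExperiment::assay(ds1),
               SummarizedExperiment::assay(sim1$dataset),
               tolerance = 1e-9)
  expect_identical(sampleGroups(ds1), sampleGroups(sim1$dataset))
  # shared hub genes are planted up-regulated in both datasets
  expect_true(all(study$shared_hubs %in% study$truth1@de_up))
  expect_true(all(study$shared_hubs %in% study$truth2@de_up))
  # apart from the pinned hubs the DE sets are disjoint
  other <- setdiff(c(study$truth2@de_up, study$truth2@de_down),
                   study$shared_hubs)
  expect_length(intersect(other, c(study$truth1@de_up,
                                   study$truth1@de_down)), 0L)
})
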