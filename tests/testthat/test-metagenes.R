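test_that("Kim-Park scores match closed-form values", {
  W <- rbind(pure = c(1, 0), uniform = c(1, 1), skew = c(3, 1))
  s <- kimParkScores(W)
  expect_equal(unname(s["pure"]), 1)
  expect_equal(unname(s["uniform"]), 0)
  expect_lt(abs(unname(s["skew"]) - 0.1887), 1e-4)
  expect_error(kimParkScores(cbind(c(1, 2))), "at least 2")
  expect_warning(s0 <- kimParkScores(rbind(c(1, 0), c(0, 0))), "all-zero")
  expect_true(is.na(s0[2]))
})

test_that("scores are invariant to positive row rescaling and normalized", {
  set.seed(3)
  W <- matrix(runif(60, 0.01, 2), 12, 5)
  s1 <- kimParkScores(W)
  s2 <- kimParkScores(W * runif(12, 0.1, 10))
  expect_equal(s1, s2, tolerance = 1e-12)
  p <- W / rowSums(W)
  expect_equal(unname(rowSums(p)), rep(1, 12), tolerance = 1e-9)
  expect_true(all(s1 >= 0 & s1 <= 1))
})

test_that("screening keeps metagene-specific genes amid a diffuse background", {
  # 10 genes load purely on metagene 1; 90 genes load uniformly
  W <- matrix(1, 90, 4)
  pure <- matrix(0, 10, 4); pure[, 1] <- 2
  W <- rbind(pure, W)
  rownames(W) <- sprintf("g%03d", seq_len(nrow(W)))
  set <- selectMetageneGenes(W)
  mem <- memberTable(set)
  s <- kimParkScores(W)
  thr <- median(s) + 3 * mad(s)
  keep <- s > thr & apply(W, 1, max) > median(W)
  expect_setequal(mem$gene, rownames(W)[keep])
  expect_setequal(mem$gene, rownames(W)[1:10])
  expect_true(all(mem$metagene == 1L))
})

test_that("degenerate screens are handled", {
  # all-uniform loadings: MAD 0, nothing exceeds the threshold strictly
  W <- matrix(1, 30, 3)
  expect_warning(set <- selectMetageneGenes(W), "no metagene member")
  expect_equal(nrow(memberTable(set)), 0L)
  # a metagene with a single surviving member is dropped
  W2 <- matrix(runif(40 * 2, 0.45, 0.55), 40, 2)
  W2[1, ] <- c(5, 0)          # lone specific gene on metagene 1
  W2[2:8, ] <- rep(c(0, 5), each = 7)  # seven specific genes on metagene 2
  rownames(W2) <- sprintf("g%02d", 1:40)
  set2 <- selectMetageneGenes(W2)
  expect_false(1L %in% memberTable(set2)$metagene)
  expect_true(all(memberTable(set2)$metagene == 2L))
})

test_that("metagenes are ranked by activation with deterministic ties", {
  members <- S4Vectors::DataFrame(
    gene = paste0("g", 1:6),
    metagene = c(1L, 1L, 2L, 2L, 3L, 3L),
    loading = c(5, 5, 1, 2, 4, 6),
    contribution = rep(1, 6),
    score = rep(1, 6))
  set <- new("MetageneSet", members = members,
             activation = c(10, 3, 10), metagene_order = order(-c(10, 3, 10)),
             n_metagenes = 3L)
  ranked <- rankMetagenes(set, top = 1L)
  mem <- memberTable(ranked)
  # activation tie between metagenes 1 and 3 resolves to the lower index
  expect_equal(mem$metagene_rank[mem$metagene == 1L][1], 1L)
  expect_equal(mem$metagene_rank[mem$metagene == 3L][1], 2L)
  expect_equal(mem$metagene_rank[mem$metagene == 2L][1], 3L)
  # members sorted by loading descending within metagene
  expect_equal(mem$loading[mem$metagene == 3L], c(6, 4))
  expect_equal(topMembers(ranked, 1)$gene[1:2], c("g1", "g6"))
})

test_that("planted metagene blocks are recovered from fitted factors", {
  hits <- 0; total <- 0
  for (seed in c(2, 5, 9)) {
    cfg <- simulationConfig(n_genes = 250, n_de_up = 60, n_de_down = 60,
                            r_true = 4, n_samples_per_group = c(8, 9),
                            noise_sd = 0.2, network_n_nodes = 120,
                            network_hub_degree = 15, seed = seed)
    sim <- simulateExpression(cfg)
    cd <- suppressMessages(collapseProbes(sim$dataset))
    de <- c(sim$truth@de_up, sim$truth@de_down)
    V <- buildTarget(cd, de)
    f <- nmfFit(V, 4, seed = seed, max_iter = 3000, tol = 1e-9)
    assigned <- max.col(basisMatrix(f), ties.method = "first")
    names(assigned) <- rownames(basisMatrix(f))
    truth_block <- sim$truth@membership[de]
    # match each planted block to the fitted component of maximum overlap
    for (q in unique(truth_block)) {
      core <- names(truth_block)[truth_block == q]
      best <- which.max(table(factor(assigned[core], levels = 1:4)))
      hits <- hits + sum(assigned[core] == as.integer(best))
      total <- total + length(core)
    }
  }
  expect_gte(hits / total, 0.8)
})
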