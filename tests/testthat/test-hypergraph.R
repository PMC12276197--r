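test_that("correlation matrix matches a longhand Pearson computation", {
  vals <- rbind(t1 = c(1, 2, 3, 4),
                b1 = c(1, 3, 2, 4),
                b2 = c(1, 2, 3, 4),    # copy of the target
                b3 = -c(1, 2, 3, 4),   # negation of the target
                b4 = rep(2, 4))        # zero variance: excluded
  colnames(vals) <- paste0("s", 1:4)
  meta <- data.frame(sample = colnames(vals), age_dpf = c(5, 5, 10, 10),
                     condition = "SC", replicate = c(1, 2, 1, 2))
  x <- expression_matrix(vals, meta)
  R <- correlation_matrix(x, "t1", c("b1", "b2", "b3", "b4"))
  # longhand: cov = 4, sds from sum of squares 5 each -> r = 0.8
  expect_equal(R["t1", "b1"], 0.8)
  expect_equal(R["t1", "b2"], 1)
  expect_equal(R["t1", "b3"], -1)
  expect_false("b4" %in% colnames(R))
  expect_error(correlation_matrix(x, "b4", "rest"), "b4")
})

test_that("binarization thresholds at one pooled sd from the pooled mean", {
  R <- matrix(c(0.9, 0.1, -0.8, 0.0, 0.05), nrow = 1,
              dimnames = list("g1", paste0("c", 1:5)))
  b <- binarize_incidence(R)
  expect_equal(b$r_mean, 0.05)
  expect_equal(b$r_sd, sqrt(1.45 / 4))   # sample sd of the five entries
  expect_equal(as.vector(b$M), c(1, 0, 1, 0, 0))

  expect_warning(b0 <- binarize_incidence(matrix(0.3, 2, 3)), "zero spread")
  expect_true(all(b0$M == 0))

  # symmetry: R and -R share a mean of zero, so marks coincide
  Rs <- matrix(c(-0.6, -0.2, 0.2, 0.6), 2, 2)
  expect_identical(binarize_incidence(Rs)$M, binarize_incidence(-Rs)$M)
})

test_that("reduced adjacency counts shared background transcripts", {
  M <- matrix(c(1, 0, 1, 1, 1, 0), 2, 3, byrow = TRUE)
  expect_equal(reduced_adjacency(M), matrix(c(2, 1, 1, 2), 2))
  expect_equal(reduced_adjacency(matrix(0, 2, 3)), matrix(0, 2, 2))
  expect_equal(reduced_adjacency(matrix(1, 2, 2)), matrix(2, 2, 2))
})

test_that("adjacency equals the brute-force shared-column count on random cases", {
  withr::local_seed(101)
  for (rep in 1:200) {
    M <- random_incidence(sample(2:8, 1), sample(2:12, 1), runif(1, 0.2, 0.8))
    H <- hypergraph_from_incidence(M)
    expect_equal(unname(H$A), unname(oracle_adjacency(M)))
  }
  # adding an all-ones background column increments every entry of A by 1
  M <- random_incidence(4, 8)
  A1 <- reduced_adjacency(M)
  A2 <- reduced_adjacency(cbind(M, ones = 1))
  expect_equal(A2, A1 + 1)
})

test_that("connectivity row sums follow the hand example and are equivariant", {
  M <- matrix(c(1, 0, 1, 1, 1, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  H <- hypergraph_from_incidence(M)
  expect_equal(unname(connectivity(H, "incidence")), c(2, 2))
  expect_equal(unname(connectivity(H, "adjacency")), c(3, 3))

  z <- hypergraph_from_incidence(matrix(0, 2, 3,
                                        dimnames = list(c("a", "b"),
                                                        c("x", "y", "z"))))
  expect_true(all(connectivity(z, "incidence") == 0))
  expect_true(all(connectivity(z, "adjacency") == 0))

  withr::local_seed(7)
  M <- random_incidence(5, 9)
  perm <- sample(5)
  H1 <- hypergraph_from_incidence(M)
  H2 <- hypergraph_from_incidence(M[perm, ])
  expect_equal(unname(connectivity(H2)), unname(connectivity(H1))[perm])
})

test_that("normalized entropy is 1 for uniform, 0 for degenerate, and matches hand values", {
  expect_equal(hypergraph_entropy(rep(3, 7)), 1)
  expect_equal(hypergraph_entropy(c(0, 5, 0)), 0)
  expect_equal(hypergraph_entropy(c(2, 1, 1)), 0.9464, tolerance = 1e-4)
  expect_equal(hypergraph_entropy(c(2, 1, 1)), oracle_entropy(c(2, 1, 1)))
  expect_error(hypergraph_entropy(c(0, 0)), "empty distribution")
  withr::local_seed(12)
  for (i in 1:50) {
    v <- rpois(sample(2:20, 1), 5) + 1
    h <- hypergraph_entropy(v)
    expect_gte(h, 0)
    expect_lte(h, 1)
  }
})

test_that("hypergraph clusters recover block structure", {
  # two disjoint blocks of shared background support
  M <- rbind(a1 = c(1, 1, 1, 0, 0, 0), a2 = c(1, 1, 1, 0, 0, 0),
             a3 = c(1, 1, 0, 0, 0, 1),
             b1 = c(0, 0, 0, 1, 1, 0), b2 = c(0, 0, 0, 1, 1, 1))
  colnames(M) <- paste0("c", 1:6)
  H <- hypergraph_from_incidence(M)
  cl <- detect_clusters(H, k = 2)
  expect_length(unique(cl[c("a1", "a2", "a3")]), 1L)
  expect_length(unique(cl[c("b1", "b2")]), 1L)
  expect_false(cl[["a1"]] == cl[["b1"]])

  expect_length(unique(detect_clusters(H, k = 5)), 5L)  # singletons
  z <- hypergraph_from_incidence(matrix(0, 3, 4))
  expect_error(detect_clusters(z), "disconnected")
})

test_that("peripheral genes are exactly the all-ones columns over the cluster", {
  M <- matrix(c(1, 0, 1, 1, 1, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  H <- hypergraph_from_incidence(M)
  expect_setequal(peripheral_genes(H, c("g1", "g2")), c("c1", "c3"))
  expect_setequal(peripheral_genes(H, "g1"), c("c1", "c3"))  # single-gene base case

  # a cluster gene with no connections makes the peripheral set empty
  M2 <- rbind(g1 = c(0, 0, 0), g2 = c(1, 1, 1))
  colnames(M2) <- paste0("c", 1:3)
  expect_length(peripheral_genes(hypergraph_from_incidence(M2),
                                 c("g1", "g2")), 0L)

  # brute-force equivalence on random instances
  withr::local_seed(33)
  for (i in 1:100) {
    M <- random_incidence(sample(2:6, 1), sample(3:10, 1))
    H <- hypergraph_from_incidence(M)
    cluster <- sample(rownames(M), sample(seq_len(nrow(M)), 1))
    expect_setequal(peripheral_genes(H, cluster),
                    oracle_peripheral(M, cluster))
  }
})

test_that("row-wise permutation preserves degrees and matches exact expectations", {
  withr::local_seed(9)
  M <- random_incidence(3, 5, 0.5)
  H <- hypergraph_from_incidence(M)
  pm <- permute_incidence(H, n_perm = 1000, seed = 4, keep_adjacency = TRUE)
  # row sums conserved in every permutation
  expect_true(all(t(pm$incidence) == rowSums(M)))
  # determinism
  pm2 <- permute_incidence(H, n_perm = 10, seed = 4)
  expect_identical(pm$adjacency[1:10, ], pm2$adjacency)

  # exact expectation of A[1,2] by exhaustive enumeration of column
  # arrangements of rows 1 and 2
  k1 <- sum(M[1, ]); k2 <- sum(M[2, ]); n <- ncol(M)
  pos1 <- utils::combn(n, k1); pos2 <- utils::combn(n, k2)
  vals <- c()
  for (i in seq_len(ncol(pos1))) {
    for (j in seq_len(ncol(pos2))) {
      vals <- c(vals, length(intersect(pos1[, i], pos2[, j])))
    }
  }
  a12 <- vapply(pm$adjacency_matrices, function(A) A[1, 2], numeric(1))
  se <- sd(vals) / sqrt(length(a12))
  expect_lt(abs(mean(a12) - mean(vals)), 3 * se + 1e-9)
})

test_that("topology comparison reports rank-sum p and fold change of means", {
  same <- compare_topology(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_equal(same$fold, 1)

  withr::local_seed(2)
  a <- rnorm(100); b <- a + 50
  expect_lt(compare_topology(a, b)$p, 1e-10)

  # exact enumeration oracle on a tiny tie-free case
  expect_equal(compare_topology(c(1, 2, 3), c(4, 5, 6))$p,
               oracle_ranksum_p(c(1, 2, 3), c(4, 5, 6)))
  expect_true(is.na(compare_topology(c(1, 2), c(-1, 1))$fold))
})
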