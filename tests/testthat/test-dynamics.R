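test_that("moving windows pair consecutive ages after sorting", {
  expect_equal(moving_windows(c(5, 10, 15, 20, 30)),
               list(c(5, 10), c(10, 15), c(15, 20), c(20, 30)))
  expect_equal(moving_windows(c(1, 2)), list(c(1, 2)))
  expect_equal(moving_windows(c(15, 5, 10)), list(c(5, 10), c(10, 15)))
  expect_error(moving_windows(7), ">= 2")
})

test_that("entropy time series honours its contract and seed", {
  st <- generate_longitudinal(synthetic_config(n_genes = 300L,
                                               genes_per_cluster = 15L,
                                               n_background_linked = 20L,
                                               seed = 3L))
  es <- entropy_timeseries(st$sc, n_targets = 30, n_iter = 20, seed = 5)
  expect_length(es, 4L)  # 5 ages -> 4 windows
  for (s in es) {
    expect_length(s$values, 20L)
    expect_true(all(s$values >= 0 & s$values <= 1))
    expect_equal(s$condition, "SC")
  }
  es2 <- entropy_timeseries(st$sc, n_targets = 30, n_iter = 20, seed = 5)
  expect_identical(lapply(es, `[[`, "values"), lapply(es2, `[[`, "values"))
  # relabelling genes changes nothing but labels
  st_rel <- st$sc
  rownames(st_rel$values) <- rev(rownames(st_rel$values))
  es3 <- entropy_timeseries(st_rel, n_targets = 30, n_iter = 20, seed = 5)
  expect_equal(lapply(es, `[[`, "values"), lapply(es3, `[[`, "values"))
})

test_that("time-series comparison separates shifted windows only", {
  withr::local_seed(6)
  mk <- function(cond, win, mu) {
    structure(list(condition = cond, window = win,
                   values = rnorm(50, mu, 0.01), n_targets = 10, seed = 1),
              class = "EntropySamples")
  }
  null_samples <- c(lapply(list(c(5, 10), c(10, 15)), mk, cond = "SC", mu = 0.8),
                    lapply(list(c(5, 10), c(10, 15)), mk, cond = "KD", mu = 0.8))
  res0 <- compare_timeseries(null_samples)
  expect_true(all(res0$p_tukey > 0.05))

  shifted <- c(lapply(list(c(5, 10), c(10, 15)), mk, cond = "SC", mu = 0.8),
               list(mk("KD", c(5, 10), 0.9), mk("KD", c(10, 15), 0.8)))
  res1 <- compare_timeseries(shifted)
  expect_lt(res1$p_tukey[res1$window == "5-10"], 1e-6)
  expect_gt(res1$p_tukey[res1$window == "10-15"], 0.05)
  expect_gt(res1$fold_kd_sc[res1$window == "5-10"], 1)

  # two-cell toy: overall F equals the longhand one-way ANOVA F
  a <- c(0.70, 0.72, 0.74); b <- c(0.80, 0.83, 0.86)
  toy <- list(structure(list(condition = "SC", window = c(5, 10), values = a,
                             n_targets = 3, seed = 1),
                        class = "EntropySamples"),
              structure(list(condition = "KD", window = c(5, 10), values = b,
                             n_targets = 3, seed = 1),
                        class = "EntropySamples"))
  res2 <- compare_timeseries(toy)
  expect_equal(res2$F[1], oracle_anova_f(c(a, b), rep(c("x", "y"), each = 3)))
})

test_that("random-walk transition matrices are row-stochastic with degree stationarity", {
  M <- matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  H <- hypergraph_from_incidence(M)
  P <- random_walk_transition(H)
  expect_equal(unname(P$P), matrix(c(0.75, 0.5, 0.25, 0.5), 2))

  # identical rows give exchangeable nodes
  M2 <- rbind(g1 = c(1, 0, 1), g2 = c(1, 0, 1))
  colnames(M2) <- paste0("c", 1:3)
  P2 <- random_walk_transition(hypergraph_from_incidence(M2))
  expect_equal(P2$P[1, ], P2$P[2, ], ignore_attr = TRUE)

  withr::local_seed(17)
  for (i in 1:30) {
    M <- random_incidence(sample(2:6, 1), sample(2:8, 1), 0.6)
    M <- M[rowSums(M) > 0, colSums(M) > 0, drop = FALSE]
    if (nrow(M) < 2) next
    H <- hypergraph_from_incidence(M)
    P <- random_walk_transition(H)
    expect_equal(unname(rowSums(P$P)), rep(1, nrow(P$P)), tolerance = 1e-9)
    # similar to a symmetric matrix: all eigenvalues real
    ev <- eigen(P$P, only.values = TRUE)$values
    expect_lt(max(abs(Im(ev))), 1e-8)
    # stationary distribution proportional to node degree, by power
    # iteration (only meaningful when the walk is irreducible)
    reach <- (P$P > 0) + 0
    paths <- reach
    for (s in seq_len(nrow(reach))) paths <- ((paths %*% reach) > 0) + reach
    if (all(paths > 0)) {
      pi0 <- rep(1 / nrow(P$P), nrow(P$P))
      for (s in 1:500) pi0 <- pi0 %*% P$P
      deg <- rowSums(H$M[P$genes, , drop = FALSE])
      expect_equal(as.vector(pi0), unname(deg / sum(deg)), tolerance = 1e-6)
    }
  }

  M3 <- rbind(g1 = c(1, 1), g2 = c(0, 0))
  colnames(M3) <- c("c1", "c2")
  expect_error(random_walk_transition(hypergraph_from_incidence(M3)), "g2")
})

test_that("transition-adjacency correlation uses off-diagonals and degrades under permutation", {
  withr::local_seed(23)
  # block-structured incidence: walk and adjacency agree
  M <- rbind(a1 = c(1, 1, 1, 0, 0), a2 = c(1, 1, 1, 0, 0),
             b1 = c(0, 0, 1, 1, 1), b2 = c(0, 0, 1, 1, 1))
  colnames(M) <- paste0("c", 1:5)
  H <- hypergraph_from_incidence(M)
  P <- random_walk_transition(H)
  r_obs <- transition_adjacency_correlation(P, H$A)
  expect_gt(r_obs, 0)

  # permuting the adjacency rows/columns lowers the correlation on average
  n <- nrow(H$A)
  perm_r <- vapply(1:100, function(i) {
    p <- sample(n)
    A <- H$A[p, p]
    dimnames(A) <- dimnames(H$A)
    transition_adjacency_correlation(P, A)
  }, numeric(1))
  expect_gt(r_obs, mean(perm_r, na.rm = TRUE))

  # 2-node boundary: exactly two off-diagonal entries
  M2 <- rbind(g1 = c(1, 1, 0), g2 = c(0, 1, 1))
  colnames(M2) <- paste0("c", 1:3)
  H2 <- hypergraph_from_incidence(M2)
  P2 <- random_walk_transition(H2)
  r2 <- transition_adjacency_correlation(P2, H2$A)
  expect_true(is.na(r2) || abs(abs(r2) - 1) < 1e-12)
})
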