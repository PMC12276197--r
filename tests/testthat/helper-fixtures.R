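# Shared fixtures and independent brute-force oracles.

# Small ExpressionMatrix built in code: n_genes x (ages x reps), pure noise
# unless a `signal` function(gene index, age) is given.
make_em <- function(n_genes = 10, ages = c(5, 10), reps = 2,
                    condition = "SC", seed = 1, signal = NULL) {
  withr::local_seed(seed)
  sample_age <- rep(ages, each = reps)
  ids <- sprintf("%s_%02d_r%d", condition, sample_age,
                 rep(seq_len(reps), times = length(ages)))
  vals <- matrix(rnorm(n_genes * length(ids), 8, 0.5), n_genes, length(ids),
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)), ids))
  if (!is.null(signal)) {
    for (i in seq_len(n_genes)) {
      vals[i, ] <- vals[i, ] + vapply(sample_age, function(a) signal(i, a),
                                      numeric(1))
    }
  }
  expression_matrix(vals, data.frame(sample = ids, age_dpf = sample_age,
                                     condition = condition,
                                     replicate = rep(seq_len(reps),
                                                     times = length(ages))))
}

random_incidence <- function(nr, nc, p = 0.4) {
  m <- matrix(rbinom(nr * nc, 1, p), nr, nc,
              dimnames = list(paste0("g", seq_len(nr)),
                              paste0("c", seq_len(nc))))
  m
}

# Brute-force oracle: A[i, j] = number of columns where rows i and j are
# both 1, counted column by column.
oracle_adjacency <- function(M) {
  n <- nrow(M)
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      A[i, j] <- sum(M[i, ] == 1 & M[j, ] == 1)
    }
  }
  dimnames(A) <- list(rownames(M), rownames(M))
  A
}

# Brute-force oracle: background columns that are all ones over the cluster
# rows, scanned one column at a time.
oracle_peripheral <- function(M, cluster_rows) {
  hits <- character(0)
  for (j in seq_len(ncol(M))) {
    if (all(M[cluster_rows, j] == 1)) hits <- c(hits, colnames(M)[j])
  }
  hits
}

# Exhaustive two-tailed Fisher p for a 2x2 table with fixed margins, by
# summing hypergeometric probabilities no larger than the observed one.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ])   # row 1 total
  n <- sum(tab[2, ])   # row 2 total
  k <- sum(tab[, 1])   # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exhaustive two-sided rank-sum p (no ties): enumerate every assignment of
# pooled ranks to group a, compare the rank-sum statistic.
oracle_ranksum_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(length(pooled), n1)
  w_all <- apply(sets, 2, function(idx) sum(r[idx]))
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Shannon entropy of a non-negative vector, normalized by log(n); written
# longhand as an independent check.
oracle_entropy <- function(x) {
  p <- x / sum(x)
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(x))
}

# One-way ANOVA F computed longhand from sums of squares.
oracle_anova_f <- function(values, groups) {
  groups <- as.factor(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  (ssb / df1) / (ssw / df2)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
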