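#' Pearson correlation of target genes against background genes
#'
#' Computes the targets x background matrix of Pearson correlation
#' coefficients across all samples of `X`. Hypergraphs for different
#' conditions are built from separate, single-condition matrices. Background
#' genes with zero variance are excluded (their correlation is undefined);
#' a zero-variance target is an error because it would drop a node.
#'
#' @param X An `ExpressionMatrix` (a single condition).
#' @param targets Target gene ids (the age-associated genes, `g`).
#' @param background Background gene ids, or `"rest"` for all genes not in
#'   `targets` (the rest of the transcriptome, the complement of `g`).
#' @return Numeric matrix of correlations, rows = targets, cols = background.
#' @export
correlation_matrix <- function(X, targets, background = "rest") {
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (ncol(X$values) < 3L) stop("need >= 3 samples to correlate")
  missing <- setdiff(targets, gene_ids(X))
  if (length(missing)) stop("unknown targets: ", paste(missing, collapse = ", "))
  if (identical(background, "rest")) {
    background <- setdiff(gene_ids(X), targets)
  } else {
    missing <- setdiff(background, gene_ids(X))
    if (length(missing)) {
      stop("unknown background genes: ", paste(missing, collapse = ", "))
    }
  }
  tv <- X$values[targets, , drop = FALSE]
  ts <- apply(tv, 1L, stats::sd)
  if (any(ts == 0)) {
    stop("zero-variance target gene(s): ",
         paste(targets[ts == 0], collapse = ", "))
  }
  bv <- X$values[background, , drop = FALSE]
  bs <- apply(bv, 1L, stats::sd)
  bv <- bv[bs > 0, , drop = FALSE]
  stats::cor(t(tv), t(bv))
}

#' Binarize a correlation matrix into a hypergraph incidence matrix
#'
#' The pooled mean and sample standard deviation over all entries of `R`
#' give one global threshold: an entry becomes 1 (edge present) when it lies
#' strictly more than one standard deviation from the pooled mean, and 0
#' otherwise. This keeps both strong positive and strong negative
#' correlations while discarding values close to the bulk.
#'
#' @param R Numeric matrix of correlations (finite, non-empty).
#' @return List with `M` (binary incidence matrix, same dimnames as `R`),
#'   `r_mean` and `r_sd` (the pooled statistics). If `r_sd` is zero the
#'   incidence is all zeros, with a warning.
#' @export
binarize_incidence <- function(R) {
  if (!is.matrix(R) || !length(R)) stop("`R` must be a non-empty matrix")
  if (!all(is.finite(R))) stop("`R` contains non-finite entries")
  r_mean <- mean(R)
  r_sd <- stats::sd(as.vector(R))
  if (r_sd == 0) {
    warning("correlation matrix has zero spread; incidence is all zeros")
    M <- array(0L, dim(R), dimnames = dimnames(R))
  } else {
    M <- (abs(R - r_mean) > r_sd) + 0L
    dim(M) <- dim(R)
    dimnames(M) <- dimnames(R)
  }
  list(M = M, r_mean = r_mean, r_sd = r_sd)
}

#' Reduced adjacency matrix of a hypergraph
#'
#' `A = M %*% t(M)`: entry (i, j) counts the background transcripts
#' correlated (after binarization) with both target genes i and j — the
#' higher-order interactions a pairwise network misses.
#'
#' @param M Binary incidence matrix.
#' @return Integer-valued symmetric matrix.
#' @export
reduced_adjacency <- function(M) {
  stopifnot(is.matrix(M), all(M %in% c(0, 1)))
  tcrossprod(M)
}

#' Build a co-expression hypergraph
#'
#' Full construction: correlate targets against the background, binarize at
#' one standard deviation from the pooled mean, and form the reduced
#' adjacency.
#'
#' @inheritParams correlation_matrix
#' @return A `Hypergraph`: list with `g` (targets), `gc` (background genes
#'   retained), `M` (incidence), `A` (reduced adjacency), `r_mean`, `r_sd`.
#' @export
build_hypergraph <- function(X, targets, background = "rest") {
  R <- correlation_matrix(X, targets, background)
  b <- binarize_incidence(R)
  structure(list(g = rownames(b$M), gc = colnames(b$M), M = b$M,
                 A = reduced_adjacency(b$M), r_mean = b$r_mean,
                 r_sd = b$r_sd),
            class = "Hypergraph")
}

#' Construct a Hypergraph from an incidence matrix
#'
#' For workflows that already hold a binary incidence matrix.
#'
#' @param M Binary incidence matrix with row names (target genes) and column
#'   names (background transcripts).
#' @param r_mean,r_sd Optional pooled binarization statistics.
#' @return A `Hypergraph`.
#' @export
hypergraph_from_incidence <- function(M, r_mean = NA_real_, r_sd = NA_real_) {
  stopifnot(is.matrix(M), all(M %in% c(0, 1)))
  if (is.null(rownames(M))) rownames(M) <- paste0("g", seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- paste0("c", seq_len(ncol(M)))
  if (length(intersect(rownames(M), colnames(M)))) {
    stop("target and background gene sets must be disjoint")
  }
  structure(list(g = rownames(M), gc = colnames(M), M = M,
                 A = reduced_adjacency(M), r_mean = r_mean, r_sd = r_sd),
            class = "Hypergraph")
}

#' @export
print.Hypergraph <- function(x, ...) {
  cat(sprintf("Hypergraph: %d target genes x %d background transcripts\n",
              length(x$g), length(x$gc)))
  cat(sprintf("  incidence density %.3f; r_mean %.3f, r_sd %.3f\n",
              mean(x$M), x$r_mean, x$r_sd))
  invisible(x)
}

#' Hypergraph connectivity
#'
#' The sum of connections of each target gene: row sums of the incidence
#' matrix (`kind = "incidence"`, connections to background transcripts) or of
#' the reduced adjacency (`kind = "adjacency"`, shared connections with other
#' targets; the diagonal — a gene's own degree — is included).
#'
#' @param H A `Hypergraph`.
#' @param kind `"adjacency"` (default) or `"incidence"`.
#' @return Named numeric vector, one entry per target gene.
#' @export
connectivity <- function(H, kind = c("adjacency", "incidence")) {
  stopifnot(inherits(H, "Hypergraph"))
  kind <- match.arg(kind)
  if (kind == "incidence") rowSums(H$M) else rowSums(H$A)
}

#' Normalized hypergraph entropy
#'
#' Shannon entropy of the connectivity vector treated as a probability
#' distribution, divided by the maximum possible entropy for the set size
#' (`log n`), giving a 0-1 measure of disorder: 1 when connections are spread
#' uniformly over the genes, 0 when concentrated on a single gene. The result
#' does not depend on the logarithm base.
#'
#' @param x Non-negative numeric vector of length >= 2, not all zero
#'   (typically a [connectivity()] vector).
#' @return Normalized entropy in `[0, 1]`.
#' @export
hypergraph_entropy <- function(x) {
  if (length(x) < 2L) stop("need a vector of length >= 2")
  if (any(x < 0)) stop("connectivity must be non-negative")
  s <- sum(x)
  if (s == 0) stop("empty distribution: all-zero connectivity")
  p <- x / s
  p <- p[p > 0]
  h <- -sum(p * log(p))
  h / log(length(x))
}

#' Topology summary of a hypergraph
#'
#' Connectivity and normalized entropy in one record. The primary entropy is
#' computed on the connectivity vector; `on = "adjacency_entries"` instead
#' uses the off-diagonal entries of the reduced adjacency (the full
#' distribution of shared correlations), exposed as an alternative reading.
#'
#' @param H A `Hypergraph`.
#' @param kind Connectivity kind, see [connectivity()].
#' @param on `"connectivity"` (default) or `"adjacency_entries"`.
#' @return List with `connectivity`, `entropy`, `n_nodes`.
#' @export
topology_summary <- function(H, kind = c("adjacency", "incidence"),
                             on = c("connectivity", "adjacency_entries")) {
  kind <- match.arg(kind)
  on <- match.arg(on)
  conn <- connectivity(H, kind)
  ent <- if (on == "connectivity") {
    hypergraph_entropy(conn)
  } else {
    hypergraph_entropy(H$A[upper.tri(H$A)])
  }
  list(connectivity = conn, entropy = ent, n_nodes = length(conn))
}

#' Detect clusters of highly interacting genes in a hypergraph
#'
#' Hierarchical clustering (average linkage) on the distance
#' `1 - A / max(A)` derived from the reduced adjacency, cut into `k`
#' clusters; `k = "auto"` chooses over 2..6 by maximum mean silhouette.
#'
#' @param H A `Hypergraph` with at least 2 target genes.
#' @param k Integer, or `"auto"`.
#' @param ages Optional named vector mapping genes to age labels (e.g. from an
#'   `AgeGeneSet`); each cluster is then annotated with the majority age of
#'   its members (attribute `"cluster_age"`).
#' @return Named integer vector gene -> cluster.
#' @export
detect_clusters <- function(H, k = "auto", ages = NULL) {
  stopifnot(inherits(H, "Hypergraph"))
  n <- length(H$g)
  if (n < 2L) stop("need >= 2 target genes")
  mx <- max(H$A)
  if (mx == 0) stop("disconnected hypergraph: adjacency is all zeros")
  D <- 1 - H$A / mx
  diag(D) <- 0
  d <- stats::as.dist(D)
  hc <- stats::hclust(d, method = "average")
  if (identical(k, "auto")) {
    ks <- 2:min(6L, n - 1L)
    sil <- vapply(ks, function(kk) {
      cl <- stats::cutree(hc, k = kk)
      if (length(unique(cl)) < 2L) return(-Inf)
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  k <- as.integer(k)
  if (k < 1L || k > n) stop("`k` out of range")
  cl <- if (k == n) stats::setNames(seq_len(n), H$g) else
    stats::cutree(hc, k = k)
  if (!is.null(ages)) {
    maj <- vapply(sort(unique(cl)), function(cc) {
      lab <- ages[names(cl)[cl == cc]]
      lab <- lab[!is.na(lab)]
      if (!length(lab)) return(NA_real_)
      as.numeric(names(sort(table(lab), decreasing = TRUE))[1L])
    }, numeric(1))
    attr(cl, "cluster_age") <- maj
  }
  cl
}

#' Peripheral gene set of a hypergraph cluster
#'
#' The background transcripts correlated (post-binarization) with every gene
#' of the cluster: the all-ones columns of the incidence matrix restricted to
#' the cluster rows. These columns, together with the cluster, form a
#' complete subgraph, implicating a wider set of genes than the initial
#' targets.
#'
#' @param H A `Hypergraph`.
#' @param cluster Non-empty subset of `H$g`.
#' @return Character vector of background gene ids (possibly empty).
#' @export
peripheral_genes <- function(H, cluster) {
  stopifnot(inherits(H, "Hypergraph"))
  if (!length(cluster)) stop("`cluster` must be non-empty")
  missing <- setdiff(cluster, H$g)
  if (length(missing)) {
    stop("cluster genes not in hypergraph: ", paste(missing, collapse = ", "))
  }
  sub <- H$M[cluster, , drop = FALSE]
  H$gc[colSums(sub) == length(cluster)]
}

#' Permutation null for hypergraph topology
#'
#' Shuffles the entries within each row of the incidence matrix independently
#' (preserving every gene's degree, hence incidence connectivity), recomputes
#' the reduced adjacency per permutation, and returns null distributions of
#' both connectivity kinds plus a rank-stability summary (Spearman
#' correlation between observed and permuted adjacency-connectivity ranks).
#' `method = "global"` instead shuffles the whole matrix, preserving only the
#' total edge count.
#'
#' @param H A `Hypergraph`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param method `"rowwise"` (default) or `"global"`.
#' @param keep_adjacency Keep the permuted adjacency matrices (memory-heavy;
#'   intended for small matrices).
#' @return List with `incidence` and `adjacency` (n_perm x n_genes null
#'   connectivity matrices), `observed` (both observed vectors),
#'   `rank_stability` (per-permutation Spearman correlations), `seed`, and
#'   optionally `adjacency_matrices`.
#' @export
permute_incidence <- function(H, n_perm = 1000L, seed = 1L,
                              method = c("rowwise", "global"),
                              keep_adjacency = FALSE) {
  stopifnot(inherits(H, "Hypergraph"), n_perm >= 1L)
  method <- match.arg(method)
  n <- length(H$g)
  obs_adj <- rowSums(H$A)
  with_seed(seed, {
    inc <- matrix(NA_real_, n_perm, n, dimnames = list(NULL, H$g))
    adj <- matrix(NA_real_, n_perm, n, dimnames = list(NULL, H$g))
    stab <- numeric(n_perm)
    mats <- if (keep_adjacency) vector("list", n_perm) else NULL
    for (b in seq_len(n_perm)) {
      Mp <- if (method == "rowwise") {
        t(apply(H$M, 1L, function(r) r[sample.int(length(r))]))
      } else {
        matrix(sample(as.vector(H$M)), nrow(H$M), ncol(H$M))
      }
      Ap <- tcrossprod(Mp)
      inc[b, ] <- rowSums(Mp)
      adj[b, ] <- rowSums(Ap)
      stab[b] <- if (stats::sd(obs_adj) == 0 || stats::sd(adj[b, ]) == 0)
        NA_real_ else stats::cor(rank(obs_adj), rank(adj[b, ]))
      if (keep_adjacency) mats[[b]] <- Ap
    }
    out <- list(incidence = inc, adjacency = adj,
                observed = list(incidence = rowSums(H$M), adjacency = obs_adj),
                rank_stability = stab, seed = seed, method = method)
    if (keep_adjacency) out$adjacency_matrices <- mats
    out
  })
}

#' Compare network topology between two groups
#'
#' Two-sided Wilcoxon rank-sum test plus the fold change of means
#' (`mean(a) / mean(b)`); the fold is reported missing when the denominator
#' mean is zero.
#'
#' @param a,b Non-empty numeric vectors (e.g. connectivity or entropy values).
#' @return List with `p` (rank-sum p-value) and `fold`.
#' @export
compare_topology <- function(a, b) {
  if (!length(a) || !length(b)) stop("both vectors must be non-empty")
  p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  fold <- if (mean(b) == 0) NA_real_ else mean(a) / mean(b)
  list(p = p, fold = fold)
}
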