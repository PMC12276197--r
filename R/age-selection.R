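#' Variance filter: keep genes with s / s_max above a threshold
#'
#' Per-gene standard deviation across all samples, divided by the maximum
#' per-gene standard deviation; genes with `s/s_max >= tau` are retained.
#' Low-variance genes are unlikely to be informative about age.
#'
#' @param X An `ExpressionMatrix`.
#' @param tau Threshold in `[0, 1]`.
#' @return Character vector of retained gene ids.
#' @export
variance_filter <- function(X, tau) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1) {
    stop("`tau` must be a single number in [0, 1]")
  }
  s <- apply(X$values, 1L, stats::sd)
  s_max <- max(s)
  if (s_max == 0) stop("no variance: all genes constant")
  ratio <- s / s_max
  keep <- if (tau == 0) ratio > 0 else ratio >= tau
  gene_ids(X)[keep]
}

#' Choose the variance-filter threshold by projection score
#'
#' For each candidate threshold, the score is the fraction of total variance
#' captured by the top-`k` principal components of the filtered submatrix,
#' minus the mean of the same quantity over `B` gene-wise permuted copies
#' (each gene's values shuffled independently across samples, destroying
#' inter-gene correlation). The threshold maximizing this
#' separation-above-null is returned; pure noise scores near zero for any
#' threshold, while thresholds isolating coordinated genes score high.
#'
#' @param X An `ExpressionMatrix`.
#' @param taus Numeric grid of candidate thresholds in `[0, 1]`.
#' @param k Number of principal components (default 4). The components must
#'   be able to span the distinct age-profile directions being sought: with
#'   fewer components than planted clusters the score keeps rising as
#'   filtering collapses onto the one or two dominant profiles, pushing the
#'   threshold into the extreme-variance tail.
#' @param B Number of permutations per threshold (default 20).
#' @param seed Integer seed for the permutation null.
#' @return List with `tau_star` (chosen threshold), `mps` (maximized
#'   projection score), `genes` (filtered gene ids at `tau_star`) and
#'   `scores` (a data frame over the grid).
#' @export
projection_score_select <- function(X, taus = seq(0.05, 0.95, by = 0.05),
                                    k = 4L, B = 20L, seed = 1L) {
  stopifnot(inherits(X, "ExpressionMatrix"), k >= 1L, B >= 1L)
  if (any(taus < 0 | taus > 1)) stop("all `taus` must lie in [0, 1]")
  top_k_frac <- function(vals) {
    # variance fraction of the top-k PCs, samples as observations
    pc <- stats::prcomp(t(vals), center = TRUE, scale. = FALSE)
    v <- pc$sdev^2
    sum(v[seq_len(min(k, length(v)))]) / sum(v)
  }
  n_samp <- ncol(X$values)
  with_seed(seed, {
    rows <- lapply(taus, function(tau) {
      genes <- variance_filter(X, tau)
      if (length(genes) < k + 1L) return(NULL)
      vals <- X$values[genes, , drop = FALSE]
      obs <- top_k_frac(vals)
      null <- vapply(seq_len(B), function(b) {
        perm <- t(apply(vals, 1L, sample_vec, size = n_samp))
        top_k_frac(perm)
      }, numeric(1))
      data.frame(tau = tau, n_genes = length(genes), observed = obs,
                 null_mean = mean(null), score = obs - mean(null))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) stop("every threshold left fewer than k + 1 genes")
    scores <- do.call(rbind, rows)
    best <- which.max(scores$score)
    list(tau_star = scores$tau[best], mps = scores$score[best],
         genes = variance_filter(X, scores$tau[best]), scores = scores)
  })
}

#' Cluster age-associated genes into age groups
#'
#' Hierarchical clustering (average linkage) on correlation distance
#' `1 - r` between mean-per-age expression profiles. With `k = "auto"` the
#' cut is chosen over `k = 2..6` by maximum mean silhouette width. Each
#' cluster is labelled with the age at which its mean profile peaks.
#'
#' @param X An `ExpressionMatrix`.
#' @param genes Gene ids to cluster (subset of `gene_ids(X)`).
#' @param k Integer number of clusters, or `"auto"`.
#' @return An `AgeGeneSet`: list with `genes`, `cluster_of` (named integer
#'   vector), `cluster_age` (named numeric vector of peak ages, names are
#'   cluster labels), `tau_star`, `mps` (NA unless filled by
#'   [select_age_genes()]).
#' @export
cluster_age_genes <- function(X, genes, k = "auto") {
  stopifnot(inherits(X, "ExpressionMatrix"))
  missing <- setdiff(genes, gene_ids(X))
  if (length(missing)) stop("unknown genes: ", paste(missing, collapse = ", "))
  if (length(genes) < 2L) stop("need at least 2 genes to cluster")
  ages <- sort(unique(X$meta$age_dpf))
  profiles <- vapply(ages, function(a) {
    rowMeans(X$values[genes, X$meta$age_dpf == a, drop = FALSE])
  }, numeric(length(genes)))
  rownames(profiles) <- genes
  cm <- suppressWarnings(stats::cor(t(profiles)))
  cm[!is.finite(cm)] <- 0  # constant profiles: maximal distance to everything
  d <- stats::as.dist(1 - cm)
  hc <- stats::hclust(d, method = "average")
  if (identical(k, "auto")) {
    ks <- 2:min(6L, length(genes) - 1L)
    sil <- vapply(ks, function(kk) {
      cl <- stats::cutree(hc, k = kk)
      if (length(unique(cl)) < 2L) return(-Inf)
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  k <- as.integer(k)
  if (k < 1L || k > length(genes)) stop("`k` out of range")
  cl <- if (k == 1L) stats::setNames(rep(1L, length(genes)), genes) else
    stats::cutree(hc, k = k)
  cluster_age <- vapply(sort(unique(cl)), function(cc) {
    prof <- colMeans(profiles[cl == cc, , drop = FALSE])
    ages[which.max(prof)]
  }, numeric(1))
  names(cluster_age) <- as.character(sort(unique(cl)))
  structure(list(genes = genes, cluster_of = cl, cluster_age = cluster_age,
                 tau_star = NA_real_, mps = NA_real_),
            class = "AgeGeneSet")
}

#' @export
print.AgeGeneSet <- function(x, ...) {
  cat(sprintf("AgeGeneSet: %d genes in %d cluster(s)",
              length(x$genes), length(x$cluster_age)))
  if (!is.na(x$tau_star)) {
    cat(sprintf(" (tau* = %.2f, MPS = %.3f)", x$tau_star, x$mps))
  }
  cat("\n")
  for (cc in names(x$cluster_age)) {
    cat(sprintf("  cluster %s: %d genes, peak age %g dpf\n", cc,
                sum(x$cluster_of == as.integer(cc)), x$cluster_age[[cc]]))
  }
  invisible(x)
}

#' Select and cluster age-associated genes in one call
#'
#' Convenience pipeline step: projection-score threshold selection followed by
#' clustering of the retained genes.
#'
#' @inheritParams projection_score_select
#' @inheritParams cluster_age_genes
#' @return An `AgeGeneSet` with `tau_star` and `mps` filled in.
#' @export
select_age_genes <- function(X, taus = seq(0.05, 0.95, by = 0.05), k = "auto",
                             pcs = 4L, B = 20L, seed = 1L) {
  sel <- projection_score_select(X, taus = taus, k = pcs, B = B, seed = seed)
  ags <- cluster_age_genes(X, sel$genes, k = k)
  ags$tau_star <- sel$tau_star
  ags$mps <- sel$mps
  ags
}

#' Per-gene one-way ANOVA of expression on age group
#'
#' Associates each gene with time-dependent expression by a classical one-way
#' ANOVA across age groups, with Benjamini-Hochberg adjustment across genes.
#' A gene that is constant within and across groups is assigned p = 1; a gene
#' with distinct group means and zero residual variance is assigned p = 0.
#'
#' @param X An `ExpressionMatrix` with at least 2 age groups of >= 2 samples.
#' @return Data frame with columns `gene`, `F`, `p`, `q`.
#' @export
anova_age_association <- function(X) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  age <- factor(X$meta$age_dpf)
  if (nlevels(age) < 2L || any(table(age) < 2L)) {
    stop("need >= 2 age groups with >= 2 samples each")
  }
  res <- t(apply(X$values, 1L, function(y) {
    if (stats::sd(y) == 0) return(c(F = NA_real_, p = 1))
    gm <- tapply(y, age, mean)
    resid_ss <- sum((y - gm[age])^2)
    if (resid_ss == 0) return(c(F = Inf, p = 0))
    ft <- stats::oneway.test(y ~ age, var.equal = TRUE)
    c(F = unname(ft$statistic), p = unname(ft$p.value))
  }))
  data.frame(gene = gene_ids(X), F = res[, "F"], p = res[, "p"],
             q = stats::p.adjust(res[, "p"], method = "BH"),
             row.names = NULL)
}

#' Rank regression of expression on age
#'
#' Per gene, a least-squares fit of rank-transformed expression on
#' rank-transformed age. `R` is the signed correlation of the fit (identical
#' to Spearman's correlation of expression with age); p-values come from the
#' usual t-test on the fitted slope, with Benjamini-Hochberg adjustment across
#' genes. Constant genes get `R = 0, p = 1` so downstream adjustment stays
#' well defined.
#'
#' @param X An `ExpressionMatrix` with >= 3 samples.
#' @param genes Genes to test (default: all).
#' @return Data frame with columns `gene`, `R`, `p`, `q`.
#' @export
rank_regression_age <- function(X, genes = gene_ids(X)) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (ncol(X$values) < 3L) stop("need >= 3 samples")
  missing <- setdiff(genes, gene_ids(X))
  if (length(missing)) stop("unknown genes: ", paste(missing, collapse = ", "))
  ry <- rank(X$meta$age_dpf)
  res <- t(vapply(genes, function(g) {
    y <- X$values[g, ]
    if (stats::sd(y) == 0) return(c(R = 0, p = 1))
    ct <- stats::cor.test(rank(y), ry)
    c(R = unname(ct$estimate), p = unname(ct$p.value))
  }, c(R = 0, p = 0)))
  data.frame(gene = genes, R = res[, "R"], p = res[, "p"],
             q = stats::p.adjust(res[, "p"], method = "BH"),
             row.names = NULL)
}
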