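#' Moving age windows
#'
#' Consecutive pairs of the (sorted, de-duplicated) age points: pooling two
#' sequential ages increases per-window sample size and damps single-age
#' variance.
#'
#' @param ages Integer vector of >= 2 distinct ages.
#' @return List of length-2 vectors `c(age1, age2)`, in order.
#' @export
moving_windows <- function(ages) {
  ages <- sort(unique(as.integer(ages)))
  if (length(ages) < 2L) stop("need >= 2 distinct ages")
  lapply(seq_len(length(ages) - 1L), function(i) ages[c(i, i + 1L)])
}

# Shared iteration engine: repeatedly sample target genes, build the
# binarized-correlation hypergraph against the remaining transcriptome and
# record normalized entropy of the adjacency connectivity. A draw whose
# targets include a zero-variance gene (or that yields an all-zero incidence)
# is retried a bounded number of times.
iterate_entropy <- function(vals, pool, n_targets, n_iter,
                            max_retries = 10L, label = "gene set") {
  sds <- apply(vals, 1L, stats::sd)
  all_genes <- rownames(vals)
  out <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      tg <- sample_vec(pool, n_targets)
      if (any(sds[tg] == 0)) next
      bg <- setdiff(all_genes, tg)
      bg <- bg[sds[bg] > 0]
      if (!length(bg)) next
      R <- stats::cor(t(vals[tg, , drop = FALSE]), t(vals[bg, , drop = FALSE]))
      b <- binarize_incidence(R)
      conn <- rowSums(tcrossprod(b$M))
      if (all(conn == 0)) next
      out[it] <- hypergraph_entropy(conn)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("could not draw a valid target set for ", label, " after ",
           max_retries, " retries")
    }
  }
  out
}

#' Moving-window hypergraph entropy time series
#'
#' Per window and iteration: `n_targets` genes are sampled uniformly without
#' replacement, correlated against the rest of the transcriptome using only
#' that window's samples, binarized, and the normalized entropy of the
#' resulting reduced-adjacency connectivity recorded. Iterating with fresh
#' random target sets turns the entropy of a fixed-size hypergraph into a
#' distribution describing the whole transcriptome's coordination in that
#' window.
#'
#' @param X An `ExpressionMatrix` (one condition).
#' @param n_targets Target genes per iteration (default 100).
#' @param n_iter Iterations per window (default 1000).
#' @param seed Integer seed.
#' @param max_retries Bounded retries for degenerate target draws.
#' @return List of `EntropySamples`, one per window: each holds `condition`,
#'   `window` (age pair), `values` (length `n_iter`, all in `[0, 1]`),
#'   `n_targets` and `seed`.
#' @export
entropy_timeseries <- function(X, n_targets = 100L, n_iter = 1000L,
                               seed = 1L, max_retries = 10L) {
  stopifnot(inherits(X, "ExpressionMatrix"), n_iter >= 1L)
  if (n_targets >= nrow(X$values)) stop("n_targets must be < number of genes")
  windows <- moving_windows(unique(X$meta$age_dpf))
  condition <- if (length(unique(X$meta$condition)) == 1L)
    unique(X$meta$condition) else "mixed"
  with_seed(seed, {
    lapply(windows, function(win) {
      samp <- X$meta$sample[X$meta$age_dpf %in% win]
      if (length(samp) < 3L) {
        stop(sprintf("window %d-%d dpf has < 3 samples", win[1L], win[2L]))
      }
      vals <- X$values[, samp, drop = FALSE]
      values <- iterate_entropy(vals, rownames(vals), n_targets, n_iter,
                                max_retries,
                                label = sprintf("window %d-%d dpf",
                                                win[1L], win[2L]))
      structure(list(condition = condition, window = win, values = values,
                     n_targets = n_targets, seed = seed),
                class = "EntropySamples")
    })
  })
}

#' @export
print.EntropySamples <- function(x, ...) {
  lab <- if (!is.null(x$window)) {
    sprintf("window %s dpf", paste(x$window, collapse = "-"))
  } else x$pathway %||% "samples"
  cat(sprintf("EntropySamples [%s, %s]: %d values, mean %.4f (seed %d)\n",
              x$condition, lab, length(x$values), mean(x$values), x$seed))
  invisible(x)
}

#' Compare entropy time series between conditions
#'
#' One-way ANOVA over all condition-by-window cells, Tukey
#' honest-significant-difference contrasts for SC vs KD within each window,
#' Benjamini-Hochberg FDR across windows, and the fold change of window
#' means (KD over SC).
#'
#' @param samples List of `EntropySamples` covering both conditions
#'   (e.g. concatenated outputs of [entropy_timeseries()] for SC and KD).
#' @return Data frame with one row per window: `window`, `F` (the overall
#'   ANOVA F), `p_tukey`, `q`, `fold_kd_sc`.
#' @export
compare_timeseries <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2L)
  df <- do.call(rbind, lapply(samples, function(s) {
    data.frame(value = s$values,
               condition = s$condition,
               window = paste(s$window, collapse = "-"),
               stringsAsFactors = FALSE)
  }))
  counts <- table(df$condition, df$window)
  if (any(counts[counts > 0] < 2L)) stop("every cell needs >= 2 values")
  if (length(unique(df$condition)) < 2L) stop("need >= 2 conditions")
  df$cell <- factor(paste(df$condition, df$window, sep = ":"))
  fit <- stats::aov(value ~ cell, data = df)
  f_stat <- summary(fit)[[1L]][["F value"]][1L]
  tk <- stats::TukeyHSD(fit)$cell
  windows <- unique(df$window)
  rows <- lapply(windows, function(w) {
    pair <- c(sprintf("SC:%s-KD:%s", w, w), sprintf("KD:%s-SC:%s", w, w))
    hit <- intersect(pair, rownames(tk))
    if (!length(hit)) return(NULL)
    kd_mean <- mean(df$value[df$condition == "KD" & df$window == w])
    sc_mean <- mean(df$value[df$condition == "SC" & df$window == w])
    data.frame(window = w, F = f_stat, p_tukey = tk[hit[1L], "p adj"],
               fold_kd_sc = if (sc_mean == 0) NA_real_ else kd_mean / sc_mean,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out$q <- stats::p.adjust(out$p_tukey, method = "BH")
  out[, c("window", "F", "p_tukey", "q", "fold_kd_sc")]
}

#' Random-walk transition matrix on a hypergraph
#'
#' Models information spreading where a walker at a node first picks an
#' incident hyperedge uniformly, then moves to a uniformly chosen member node
#' of that edge (self-transitions allowed): with `M_c` the cluster-restricted
#' incidence, `D_v` the diagonal of node degrees and `D_e` of edge sizes,
#' `P = D_v^-1 M_c D_e^-1 M_c^t`. Rows sum to one by construction, and the
#' stationary distribution is proportional to node degree.
#'
#' @param H A `Hypergraph`.
#' @param cluster Subset of `H$g` to restrict the walk to (default: all).
#' @return A `TransitionMatrix`: list with `genes` and the row-stochastic
#'   matrix `P`.
#' @export
random_walk_transition <- function(H, cluster = H$g) {
  stopifnot(inherits(H, "Hypergraph"))
  missing <- setdiff(cluster, H$g)
  if (length(missing)) {
    stop("cluster genes not in hypergraph: ", paste(missing, collapse = ", "))
  }
  Mc <- H$M[cluster, , drop = FALSE]
  Mc <- Mc[, colSums(Mc) > 0, drop = FALSE]
  deg <- rowSums(Mc)
  if (any(deg == 0)) {
    stop("disconnected: isolated genes ",
         paste(cluster[deg == 0], collapse = ", "))
  }
  if (!ncol(Mc)) stop("disconnected: no incident hyperedges")
  esize <- colSums(Mc)
  P <- (Mc / deg) %*% t(Mc / rep(esize, each = nrow(Mc)))
  dimnames(P) <- list(cluster, cluster)
  structure(list(genes = cluster, P = P), class = "TransitionMatrix")
}

#' @export
print.TransitionMatrix <- function(x, ...) {
  cat(sprintf("TransitionMatrix: %d nodes (row-stochastic)\n",
              length(x$genes)))
  invisible(x)
}

#' Correlation between random-walk transitions and hypergraph adjacency
#'
#' Pearson correlation between the flattened off-diagonal entries of the
#' transition matrix and of the reduced adjacency, quantifying how much of
#' the walk's structure the (undirected) adjacency already captures. Both
#' diagonals are structurally inflated and are excluded.
#'
#' @param P A `TransitionMatrix`.
#' @param A Square adjacency matrix over the same genes, in the same order
#'   (e.g. `H$A` restricted to the cluster).
#' @return Pearson r, or `NA` when either off-diagonal vector is constant.
#' @export
transition_adjacency_correlation <- function(P, A) {
  stopifnot(inherits(P, "TransitionMatrix"), is.matrix(A))
  if (!identical(dim(A), dim(P$P))) stop("dimension mismatch")
  if (!is.null(rownames(A)) && !identical(rownames(A), P$genes)) {
    stop("`A` must cover the same genes in the same order as `P`")
  }
  off <- !diag(TRUE, nrow(A))
  p_off <- P$P[off]
  a_off <- A[off]
  if (stats::sd(p_off) == 0 || stats::sd(a_off) == 0) return(NA_real_)
  stats::cor(p_off, a_off)
}
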