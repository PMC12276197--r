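#' Configuration for the synthetic longitudinal study generator
#'
#' Defines a two-condition (control-like "SC", knockdown-like "KD")
#' longitudinal design with planted age-associated gene clusters, background
#' genes correlated with cluster genes, and a condition effect that disrupts
#' the earliest cluster and raises cross-cluster correlation.
#'
#' @param n_genes Total number of genes (default 2000).
#' @param ages Ordered developmental ages in days post fertilisation
#'   (default `c(5, 10, 15, 20, 30)`).
#' @param n_reps Replicates per age and condition (default 3).
#' @param n_clusters Number of planted age clusters (default 4). Clusters are
#'   assigned consecutive age windows; the last cluster absorbs the remaining
#'   ages (with the defaults: 5, 10, 15 and 20-30 dpf).
#' @param genes_per_cluster Genes per planted cluster (default 40).
#' @param n_background_linked Background genes correlated with each cluster
#'   (default 100 per cluster).
#' @param effect_size Log2 up-shift of a cluster gene at its assigned ages
#'   (default 2).
#' @param background_corr Target Pearson correlation between a linked
#'   background gene and its parent cluster gene (default 0.8).
#' @param noise_sd Per-sample log2 noise standard deviation (default 0.5).
#' @param kd_disruption Fraction of earliest-cluster genes whose peak age is
#'   reassigned in the KD-like condition (default 0.7).
#' @param kd_crosstalk Cross-cluster profile mixing added in the KD-like
#'   condition, in `[0, 1]` (default 0.3).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#'
#' @return A validated `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_genes = 2000L, ages = c(5L, 10L, 15L, 20L, 30L),
                             n_reps = 3L, n_clusters = 4L,
                             genes_per_cluster = 40L,
                             n_background_linked = 100L, effect_size = 2,
                             background_corr = 0.8, noise_sd = 0.5,
                             kd_disruption = 0.7, kd_crosstalk = 0.3,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), ages = sort(as.integer(ages)),
              n_reps = as.integer(n_reps), n_clusters = as.integer(n_clusters),
              genes_per_cluster = as.integer(genes_per_cluster),
              n_background_linked = as.integer(n_background_linked),
              effect_size = effect_size, background_corr = background_corr,
              noise_sd = noise_sd, kd_disruption = kd_disruption,
              kd_crosstalk = kd_crosstalk, seed = as.integer(seed))
  planted <- cfg$n_clusters * (cfg$genes_per_cluster + cfg$n_background_linked)
  if (planted > cfg$n_genes) {
    stop("planted genes (", planted, ") exceed n_genes (", cfg$n_genes, ")")
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$background_corr <= 0 || cfg$background_corr > 1) {
    stop("background_corr must be in (0, 1]")
  }
  if (cfg$kd_disruption < 0 || cfg$kd_disruption > 1) {
    stop("kd_disruption must be in [0, 1]")
  }
  if (cfg$kd_crosstalk < 0 || cfg$kd_crosstalk > 1) {
    stop("kd_crosstalk must be in [0, 1]")
  }
  if (length(cfg$ages) < 2L) stop("need at least two ages")
  if (cfg$n_clusters > length(cfg$ages)) {
    stop("n_clusters cannot exceed the number of ages")
  }
  structure(cfg, class = "SyntheticConfig")
}

# Consecutive age windows for the planted clusters; the last window absorbs
# any leftover ages (4 clusters over 5 ages -> {5}, {10}, {15}, {20,30}).
cluster_age_windows <- function(ages, n_clusters) {
  windows <- lapply(seq_len(n_clusters - 1L), function(c) ages[c])
  windows[[n_clusters]] <- ages[n_clusters:length(ages)]
  windows
}

#' Generate a two-condition longitudinal expression study
#'
#' Expression model, on the log2 scale: gene value = per-gene baseline
#' `N(8, 1)` + age-profile shift + `N(0, noise_sd)` noise. A cluster gene's
#' age profile is a boxcar: elevated by `effect_size` at its assigned ages
#' only. Each linked background gene is `rho * z(parent) + sqrt(1 - rho^2) *
#' noise`, scaled to `noise_sd`, so the complete-subgraph peripheral structure
#' exists by construction. In the KD-like condition a `kd_disruption` fraction
#' of earliest-cluster genes have their peak reassigned to a random other age,
#' and a `kd_crosstalk` fraction of cluster genes additionally adopt a second
#' cluster's age profile ("bridging" genes), adding cross-cluster correlation.
#'
#' All random draws happen before assembly, so matrices for different
#' `kd_crosstalk` values under the same seed share their noise exactly.
#'
#' @param cfg A [synthetic_config()].
#' @return A `SyntheticStudy` list: `sc` and `kd` (both `ExpressionMatrix`),
#'   `truth` (data frame: gene, role in cluster/linked/noise, cluster, parent,
#'   disrupted, kd_peak_age) and `config`.
#' @export
generate_longitudinal <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  with_seed(cfg$seed, {
    n_samples <- length(cfg$ages) * cfg$n_reps
    sample_age <- rep(cfg$ages, each = cfg$n_reps)
    sample_rep <- rep(seq_len(cfg$n_reps), times = length(cfg$ages))
    genes <- sprintf("gene_%04d", seq_len(cfg$n_genes))
    windows <- cluster_age_windows(cfg$ages, cfg$n_clusters)

    n_cluster_genes <- cfg$n_clusters * cfg$genes_per_cluster
    n_linked <- cfg$n_clusters * cfg$n_background_linked
    role <- rep("noise", cfg$n_genes)
    role[seq_len(n_cluster_genes)] <- "cluster"
    role[n_cluster_genes + seq_len(n_linked)] <- "linked"
    cluster <- rep(NA_integer_, cfg$n_genes)
    cluster[seq_len(n_cluster_genes)] <-
      rep(seq_len(cfg$n_clusters), each = cfg$genes_per_cluster)
    cluster[n_cluster_genes + seq_len(n_linked)] <-
      rep(seq_len(cfg$n_clusters), each = cfg$n_background_linked)

    # --- all random draws, in fixed order -------------------------------
    baseline <- stats::rnorm(cfg$n_genes, mean = 8, sd = 1)
    parent <- rep(NA_character_, cfg$n_genes)
    linked_idx <- which(role == "linked")
    for (c in seq_len(cfg$n_clusters)) {
      members <- genes[role == "cluster" & cluster == c]
      kids <- linked_idx[cluster[linked_idx] == c]
      parent[kids] <- members[sample.int(length(members), length(kids),
                                         replace = TRUE)]
    }
    first_cluster <- which(role == "cluster" & cluster == 1L)
    n_disrupt <- round(cfg$kd_disruption * length(first_cluster))
    disrupted_idx <- if (n_disrupt > 0L) {
      sort(sample_vec(first_cluster, n_disrupt))
    } else integer(0)
    other_ages <- setdiff(cfg$ages, windows[[1L]])
    kd_peak <- rep(NA_integer_, cfg$n_genes)
    if (n_disrupt > 0L && length(other_ages)) {
      pool <- rep(other_ages, length.out = max(n_disrupt, length(other_ages)))
      kd_peak[disrupted_idx] <- sample_vec(pool, n_disrupt)
    } else {
      disrupted_idx <- integer(0)
    }
    noise_sc <- matrix(stats::rnorm(cfg$n_genes * n_samples, 0, cfg$noise_sd),
                       cfg$n_genes, n_samples)
    noise_kd <- matrix(stats::rnorm(cfg$n_genes * n_samples, 0, cfg$noise_sd),
                       cfg$n_genes, n_samples)
    link_noise_sc <- matrix(stats::rnorm(n_linked * n_samples),
                            n_linked, n_samples)
    link_noise_kd <- matrix(stats::rnorm(n_linked * n_samples),
                            n_linked, n_samples)
    cluster_idx <- which(role == "cluster")
    n_bridge <- round(cfg$kd_crosstalk * length(cluster_idx))
    bridge_idx <- if (n_bridge > 0L && cfg$n_clusters > 1L) {
      sort(sample_vec(cluster_idx, n_bridge))
    } else integer(0)
    bridge_to <- rep(NA_integer_, cfg$n_genes)
    for (i in bridge_idx) {
      bridge_to[i] <- sample_vec(setdiff(seq_len(cfg$n_clusters),
                                         cluster[i]), 1L)
    }

    # --- deterministic assembly -----------------------------------------
    boxcar <- function(win) cfg$effect_size * (sample_age %in% win)
    sc_profile <- matrix(0, cfg$n_genes, n_samples)
    kd_profile <- matrix(0, cfg$n_genes, n_samples)
    cluster_profiles <- t(vapply(windows, boxcar, numeric(n_samples)))
    # Crosstalk: a kd_crosstalk fraction of cluster genes additionally adopt
    # a second, randomly chosen cluster's age profile in the KD condition.
    # These bridging genes co-express strongly (above the binarization
    # threshold) with the other cluster and its linked background genes,
    # raising cross-cluster correlation by construction.
    for (i in cluster_idx) {
      c <- cluster[i]
      sc_profile[i, ] <- cluster_profiles[c, ]
      own_kd <- if (i %in% disrupted_idx) boxcar(kd_peak[i]) else
        cluster_profiles[c, ]
      kd_profile[i, ] <- own_kd
      if (!is.na(bridge_to[i])) {
        kd_profile[i, ] <- kd_profile[i, ] + cluster_profiles[bridge_to[i], ]
      }
    }

    assemble <- function(noise, profile, link_noise) {
      vals <- baseline + profile + noise
      rownames(vals) <- genes
      # linked genes: correlated copy of the parent at noise amplitude
      rho <- cfg$background_corr
      for (k in seq_along(linked_idx)) {
        i <- linked_idx[k]
        p <- vals[parent[i], ]
        z <- (p - mean(p)) / stats::sd(p)
        vals[i, ] <- baseline[i] +
          cfg$noise_sd * (rho * z + sqrt(1 - rho^2) * link_noise[k, ])
      }
      vals
    }
    sc_vals <- assemble(noise_sc, sc_profile, link_noise_sc)
    kd_vals <- assemble(noise_kd, kd_profile, link_noise_kd)

    make_em <- function(vals, condition) {
      ids <- sprintf("%s_%02d_r%d", condition, sample_age, sample_rep)
      colnames(vals) <- ids
      expression_matrix(vals, data.frame(sample = ids, age_dpf = sample_age,
                                         condition = condition,
                                         replicate = sample_rep))
    }
    truth <- data.frame(gene = genes, role = role, cluster = cluster,
                        parent = parent,
                        disrupted = seq_len(cfg$n_genes) %in% disrupted_idx,
                        kd_peak_age = kd_peak, bridge_to = bridge_to,
                        stringsAsFactors = FALSE)
    structure(list(sc = make_em(sc_vals, "SC"), kd = make_em(kd_vals, "KD"),
                   truth = truth, config = cfg),
              class = "SyntheticStudy")
  })
}

#' @export
print.SyntheticStudy <- function(x, ...) {
  cat(sprintf("SyntheticStudy: %d genes, ages %s dpf, %d reps, seed %d\n",
              x$config$n_genes, paste(x$config$ages, collapse = "/"),
              x$config$n_reps, x$config$seed))
  cat(sprintf("  planted: %d clusters x %d genes, %d linked background genes\n",
              x$config$n_clusters, x$config$genes_per_cluster,
              sum(x$truth$role == "linked")))
  invisible(x)
}
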