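#' Construct an ExpressionMatrix
#'
#' The central data container of the package: a genes x samples matrix of
#' normalized log2 expression values together with per-sample metadata
#' (developmental age in days post fertilisation, condition, replicate).
#'
#' @param values Numeric matrix, genes in rows and samples in columns.
#'   Row names are gene ids, column names are sample ids; both must be unique
#'   and non-missing.
#' @param meta Data frame with columns `sample`, `age_dpf`, `condition`
#'   (one of `"SC"` or `"KD"`) and `replicate` (integer >= 1). Exactly one row
#'   per sample; rows are reordered to match the column order of `values`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `meta` (the aligned metadata data frame).
#'
#' @examples
#' vals <- matrix(rnorm(6, 8), 2, 3,
#'                dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' meta <- data.frame(sample = c("s1", "s2", "s3"), age_dpf = c(5, 5, 10),
#'                    condition = "SC", replicate = c(1, 2, 1))
#' x <- expression_matrix(vals, meta)
#' dim(x)
#' @export
expression_matrix <- function(values, meta) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || anyNA(gene_ids) || any(gene_ids == "")) {
    stop("`values` must have non-empty row names (gene ids)")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (is.null(sample_ids) || anyDuplicated(sample_ids)) {
    stop("`values` must have unique column names (sample ids)")
  }
  if (anyNA(values)) stop("`values` contains missing entries")
  required <- c("sample", "age_dpf", "condition", "replicate")
  if (!is.data.frame(meta) || !all(required %in% names(meta))) {
    stop("`meta` must be a data frame with columns ",
         paste(required, collapse = ", "))
  }
  missing_meta <- setdiff(sample_ids, meta$sample)
  extra_meta <- setdiff(meta$sample, sample_ids)
  if (length(missing_meta)) {
    stop("samples missing from metadata: ", paste(missing_meta, collapse = ", "))
  }
  if (length(extra_meta)) {
    stop("metadata lists samples absent from the matrix: ",
         paste(extra_meta, collapse = ", "))
  }
  if (anyDuplicated(meta$sample)) {
    stop("duplicate sample ids in metadata")
  }
  meta <- meta[match(sample_ids, meta$sample), required, drop = FALSE]
  rownames(meta) <- NULL
  meta$age_dpf <- as.integer(meta$age_dpf)
  meta$replicate <- as.integer(meta$replicate)
  if (anyNA(meta$age_dpf)) stop("`age_dpf` must be integer-valued")
  if (!all(meta$condition %in% c("SC", "KD"))) {
    stop("`condition` must be one of \"SC\", \"KD\"")
  }
  if (anyNA(meta$replicate) || any(meta$replicate < 1L)) {
    stop("`replicate` must be an integer >= 1")
  }
  structure(list(values = values, meta = meta), class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("ages (dpf):", paste(sort(unique(x$meta$age_dpf)), collapse = ", "), "\n")
  cat("conditions:", paste(unique(x$meta$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Gene and sample ids of an ExpressionMatrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Restrict an ExpressionMatrix to a subset of samples
#'
#' @param x An `ExpressionMatrix`.
#' @param samples Character vector of sample ids to keep.
#' @return An `ExpressionMatrix` containing only those samples.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  missing <- setdiff(samples, sample_ids(x))
  if (length(missing)) {
    stop("unknown samples: ", paste(missing, collapse = ", "))
  }
  expression_matrix(x$values[, samples, drop = FALSE],
                    x$meta[x$meta$sample %in% samples, , drop = FALSE])
}

#' Read an expression matrix and its sample metadata from TSV files
#'
#' The matrix file is tab-separated with a header row of sample ids and gene
#' ids in the first column; the metadata file has columns `sample`, `age_dpf`,
#' `condition`, `replicate`. Downstream modules consume only the returned
#' object and never re-parse files.
#'
#' @param matrix_path Path to the expression TSV.
#' @param meta_path Path to the metadata TSV.
#' @param missing Policy for genes with missing values: `"drop_gene"` (default)
#'   removes the offending rows, `"fail"` raises an error.
#'
#' @return An [expression_matrix()].
#' @export
read_expression <- function(matrix_path, meta_path,
                            missing = c("drop_gene", "fail")) {
  missing <- match.arg(missing)
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("matrix file must have gene ids plus >= 1 sample")
  gene <- as.character(raw[[1L]])
  if (anyDuplicated(gene)) {
    stop("duplicate gene ids in ", matrix_path, ": ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "))
  }
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "" & col != "NA")
      if (length(bad)) {
        stop(sprintf("non-numeric value '%s' at row %d (gene %s), column %s",
                     col[bad[1L]], bad[1L], gene[bad[1L]], names(vals)[j]))
      }
      vals[[j]] <- num
    }
  }
  values <- as.matrix(vals)
  rownames(values) <- gene
  if (anyNA(values)) {
    if (missing == "fail") {
      bad <- which(rowSums(is.na(values)) > 0L)
      stop("missing values in genes: ",
           paste(utils::head(gene[bad], 5L), collapse = ", "))
    }
    values <- values[rowSums(is.na(values)) == 0L, , drop = FALSE]
  }
  meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expression_matrix(values, meta)
}

#' Write an expression matrix and metadata to TSV files
#'
#' Inverse of [read_expression()]: `read(write(x))` reproduces the content of
#' `x` up to floating-point formatting.
#'
#' @param x An `ExpressionMatrix`.
#' @param matrix_path Output path for the expression TSV.
#' @param meta_path Output path for the metadata TSV.
#' @return Invisibly, `x`.
#' @export
write_expression <- function(x, matrix_path, meta_path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(gene = gene_ids(x), x$values, check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read gene-set collections in GMT format
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Pathway order is preserved.
#'
#' @param gmt_path Path to the GMT file.
#' @return A `PathwayCollection`: list with `pathways` (named list of gene-id
#'   vectors) and `source` (the input path). An empty file yields an empty
#'   collection.
#' @export
read_gene_sets <- function(gmt_path) {
  lines <- readLines(gmt_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  pathways <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 gene",
                   i, length(fields)))
    }
    name <- fields[1L]
    if (name %in% names(pathways)) {
      stop("duplicate pathway name: ", name)
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop(sprintf("GMT line %d has an empty gene list", i))
    pathways[[name]] <- genes
  }
  structure(list(pathways = pathways, source = gmt_path),
            class = "PathwayCollection")
}

#' @export
print.PathwayCollection <- function(x, ...) {
  cat(sprintf("PathwayCollection: %d pathway(s) from %s\n",
              length(x$pathways), x$source %||% "<memory>"))
  invisible(x)
}

#' Construct a PathwayCollection from a named list
#' @param pathways Named list of gene-id vectors; names must be unique and
#'   lists non-empty.
#' @param source Free-text provenance label.
#' @return A `PathwayCollection`.
#' @export
pathway_collection <- function(pathways, source = "<memory>") {
  stopifnot(is.list(pathways))
  if (length(pathways)) {
    if (is.null(names(pathways)) || anyDuplicated(names(pathways))) {
      stop("pathway names must be unique and non-missing")
    }
    if (any(!lengths(pathways))) stop("pathway gene lists must be non-empty")
  }
  structure(list(pathways = pathways, source = source),
            class = "PathwayCollection")
}

#' Read a two-column homolog map (TSV, columns from/to)
#'
#' @param path Path to a tab-separated file with a header row and two columns
#'   (source id, target id). Many-to-many mappings are allowed.
#' @return Data frame with columns `from` and `to`.
#' @export
read_homolog_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("homolog map needs two columns (from, to)")
  out <- data.frame(from = as.character(df[[1L]]), to = as.character(df[[2L]]),
                    stringsAsFactors = FALSE)
  out[nzchar(out$from) & nzchar(out$to), , drop = FALSE]
}

#' Run configuration for the stochastic stages of the pipeline
#'
#' Collects the seed and the iteration counts / thresholds used by every
#' randomized stage, so that a whole analysis is reproducible from one record.
#'
#' @param seed Integer seed used by all stochastic stages.
#' @param n_perm Permutations for the incidence-matrix null.
#' @param n_targets,n_iter Target-set size and iteration count for the
#'   moving-window entropy time series.
#' @param pathway_n_genes,pathway_n_iter Per-pathway hypergraph size and
#'   iteration count.
#' @param n_draws Posterior draws for the Bayesian entropy comparison.
#' @param min_pathway_genes Minimum surviving genes for a pathway to be kept.
#' @return A classed list with the validated settings.
#' @export
run_config <- function(seed = 1L, n_perm = 1000L, n_targets = 100L,
                       n_iter = 1000L, pathway_n_genes = 10L,
                       pathway_n_iter = 1000L, n_draws = 4000L,
                       min_pathway_genes = 15L) {
  counts <- c(n_perm = n_perm, n_targets = n_targets, n_iter = n_iter,
              pathway_n_genes = pathway_n_genes,
              pathway_n_iter = pathway_n_iter, n_draws = n_draws,
              min_pathway_genes = min_pathway_genes)
  if (any(counts < 1L)) {
    stop("all iteration counts must be >= 1; offending: ",
         paste(names(counts)[counts < 1L], collapse = ", "))
  }
  structure(list(seed = as.integer(seed), n_perm = as.integer(n_perm),
                 n_targets = as.integer(n_targets), n_iter = as.integer(n_iter),
                 pathway_n_genes = as.integer(pathway_n_genes),
                 pathway_n_iter = as.integer(pathway_n_iter),
                 n_draws = as.integer(n_draws),
                 min_pathway_genes = as.integer(min_pathway_genes)),
            class = "RunConfig")
}
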