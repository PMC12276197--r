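#' Normalized descending ranks
#'
#' Ranks row sums in descending order with ties averaged, then rescales as
#' `(n - rank) / (n - 1)` so the most connected gene maps to 1 and the least
#' connected to 0. Invariant to multiplying the input by a positive constant.
#'
#' @param row_sums Numeric vector of length >= 2.
#' @return Numeric vector in `[0, 1]`, same names as the input.
#' @export
normalized_rank <- function(row_sums) {
  n <- length(row_sums)
  if (n < 2L) stop("need >= 2 values to rank")
  r <- rank(-row_sums, ties.method = "average")
  out <- (n - r) / (n - 1)
  names(out) <- names(row_sums)
  out
}

#' Row sums and normalized ranks for a hypergraph
#'
#' Per target gene and matrix kind (incidence and reduced adjacency), the row
#' sum — a gene's number of (shared) connections, its importance in the
#' network — and its normalized rank.
#'
#' @param H A `Hypergraph`.
#' @param condition Optional condition label carried into the table.
#' @return A `RankTable` data frame: `gene`, `condition`, `matrix_kind`,
#'   `row_sum`, `norm_rank`.
#' @export
rank_table <- function(H, condition = NA_character_) {
  stopifnot(inherits(H, "Hypergraph"))
  rows <- lapply(c("incidence", "adjacency"), function(kind) {
    rs <- connectivity(H, kind)
    data.frame(gene = H$g, condition = condition, matrix_kind = kind,
               row_sum = as.numeric(rs), norm_rank = normalized_rank(rs),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  structure(do.call(rbind, rows), class = c("RankTable", "data.frame"))
}

#' Compare normalized ranks of genes between two conditions
#'
#' For each requested gene, the normalized rank in the SC and KD tables and
#' their difference (`delta = KD - SC`); a positive delta means the gene
#' gained importance after knockdown. Genes missing from either table are
#' reported in the `"skipped"` attribute, not silently dropped.
#'
#' @param genes Gene ids to compare (e.g. GWAS genes).
#' @param sc,kd `RankTable` objects (see [rank_table()]).
#' @param kind `"incidence"` or `"adjacency"`.
#' @return Data frame `gene`, `norm_rank_sc`, `norm_rank_kd`, `delta`, with
#'   attribute `"skipped"` listing absent genes.
#' @export
rank_shift <- function(genes, sc, kd, kind = c("incidence", "adjacency")) {
  kind <- match.arg(kind)
  sc <- sc[sc$matrix_kind == kind, ]
  kd <- kd[kd$matrix_kind == kind, ]
  present <- genes %in% sc$gene & genes %in% kd$gene
  skipped <- genes[!present]
  if (length(skipped)) {
    message("skipping genes absent from a rank table: ",
            paste(skipped, collapse = ", "))
  }
  genes <- genes[present]
  out <- data.frame(gene = genes,
                    norm_rank_sc = sc$norm_rank[match(genes, sc$gene)],
                    norm_rank_kd = kd$norm_rank[match(genes, kd$gene)],
                    stringsAsFactors = FALSE)
  out$delta <- out$norm_rank_kd - out$norm_rank_sc
  attr(out, "skipped") <- skipped
  out
}

#' Enrichment of annotated genes in a query set (Fisher's exact test)
#'
#' Builds the 2x2 table `[[hits, query - hits], [background hits,
#' background - background hits]]` and reports the sample odds ratio
#' (`ad / bc`) with the two-tailed Fisher exact p-value. The conditional
#' maximum-likelihood odds ratio from the exact test is also returned.
#'
#' @param hits_in_query Annotated genes among the query.
#' @param query_size Size of the query set.
#' @param background_hits Annotated genes in the background.
#' @param background_size Size of the background (query genes are not
#'   removed from it).
#' @return List with `odds_ratio` (sample OR), `p` (two-tailed Fisher),
#'   `conditional_or`, `table`, and `note` (set when a zero off-diagonal cell
#'   makes the sample OR infinite or zero).
#' @export
gwas_enrichment_test <- function(hits_in_query, query_size, background_hits,
                                 background_size) {
  counts <- c(hits_in_query, query_size, background_hits, background_size)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (hits_in_query > query_size || background_hits > background_size) {
    stop("impossible counts: hits exceed set size")
  }
  tab <- matrix(c(hits_in_query, query_size - hits_in_query,
                  background_hits, background_size - background_hits),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("query", "background"), c("hit", "miss")))
  a <- tab[1L, 1L]; b <- tab[1L, 2L]; c <- tab[2L, 1L]; d <- tab[2L, 2L]
  note <- NULL
  or <- if (b == 0 || c == 0) {
    note <- "zero off-diagonal cell: sample odds ratio is infinite"
    Inf
  } else if (a == 0 || d == 0) {
    note <- "zero diagonal cell: sample odds ratio is zero"
    0
  } else (a * d) / (b * c)
  ft <- stats::fisher.test(tab)
  list(odds_ratio = or, p = ft$p.value,
       conditional_or = unname(ft$estimate), table = tab, note = note)
}
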