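#' Hypergeometric overrepresentation analysis
#'
#' Upper-tail hypergeometric test of a query gene list against each gene
#' set, with Benjamini-Hochberg adjustment across sets:
#' `p = P(X >= overlap)` for `X ~ Hypergeometric(universe, set, query)`.
#' Query genes outside the universe are dropped with a warning; set members
#' outside the universe are ignored.
#'
#' @param query character vector of gene symbols.
#' @param gene_sets named list of character vectors.
#' @param universe character vector of background genes (all annotated
#'   genes).
#' @return data frame sorted by p: `set`, `set_size`, `overlap`,
#'   `universe_size`, `query_size`, `p`, `p_adj`, `overlap_genes`.
#' @export
hypergeometric_ora <- function(query, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe); k <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    ov <- intersect(set, query)
    p <- stats::phyper(length(ov) - 1, length(set), N - length(set), k,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = length(ov),
               universe_size = N, query_size = k, p = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_pvalues(out$p)
  out <- out[order(out$p), c("set", "set_size", "overlap", "universe_size",
                             "query_size", "p", "p_adj", "overlap_genes")]
  rownames(out) <- NULL
  out
}

#' Top enriched terms report
#'
#' First `k` sets surviving the adjusted-p reporting cutoff (default 0.25),
#' with the gene-ratio column computed as overlap / set size.
#'
#' @param results data frame from [hypergeometric_ora()] (sorted by p).
#' @param k maximum number of terms (default 15).
#' @param padj_max adjusted-p reporting cutoff.
#' @export
top_terms <- function(results, k = 15, padj_max = 0.25) {
  out <- results[results$p_adj < padj_max, , drop = FALSE]
  out <- utils::head(out, k)
  out$gene_ratio <- ifelse(out$set_size > 0, out$overlap / out$set_size, 0)
  rownames(out) <- NULL
  out
}
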