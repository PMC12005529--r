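#' Claudin-family gene symbols
#'
#' Default include-list for the prioritization cascade: the human claudin
#' family, whose tight-junction biology is central to the disease. At
#' minimum CLDN17 must be present.
#' @export
claudin_family <- function() {
  paste0("CLDN", c(1:12, 14:20, 22:25))
}

#' Configuration of the candidate-prioritization cascade
#'
#' @param alpha raw gene-scan p-value threshold (default 0.01).
#' @param gwas_p_max maximum GWAS-catalog association p-value for a trait
#'   match (default 1e-6).
#' @param require_both_evidence require both RNA and protein kidney
#'   expression evidence in round 1 (default TRUE).
#' @param include_genes genes added to the candidate set whenever they pass
#'   the significance threshold, regardless of expression or trait match.
#' @export
prioritization_config <- function(alpha = 0.01, gwas_p_max = 1e-6,
                                  require_both_evidence = TRUE,
                                  include_genes = claudin_family()) {
  stopifnot(alpha > 0, alpha < 1, gwas_p_max > 0, gwas_p_max < 1)
  if (!"CLDN17" %in% include_genes) {
    include_genes <- c(include_genes, "CLDN17")
  }
  structure(list(alpha = alpha, gwas_p_max = gwas_p_max,
                 require_both_evidence = require_both_evidence,
                 include_genes = toupper(include_genes)),
            class = "prioritization_config")
}

#' Significance filter on the gene scan
#'
#' @param scan gene-scan results data frame (columns `gene`, `p`).
#' @param alpha raw p-value threshold.
#' @return the significant subset ordered by p.
#' @export
filter_significant <- function(scan, alpha = 0.01) {
  out <- scan[scan$p < alpha, , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kidney-expression filter
#'
#' Retains genes whose expression table flags are TRUE (both RNA and
#' protein evidence by default). Genes absent from the table are treated
#' as not expressed, with a warning.
#'
#' @param genes character vector of gene symbols.
#' @param bundle an [annotation_bundle()].
#' @param require_both require both evidence flags (else RNA alone).
#' @export
filter_expression <- function(genes, bundle, require_both = TRUE) {
  expr <- bundle$expression
  idx <- match(toupper(genes), toupper(expr$gene))
  absent <- is.na(idx)
  if (any(absent)) {
    warning(sum(absent), " gene(s) absent from the expression table, ",
            "treated as not expressed")
  }
  ok <- !absent &
    (expr$rna_evidence[idx] %in% TRUE) &
    (!require_both | expr$protein_evidence[idx] %in% TRUE)
  genes[ok]
}

#' Match genes against curated-trait GWAS-catalog associations
#'
#' A gene matches when any catalog association maps to it with a trait in
#' the curated list and association p below `gwas_p_max`. Matching joins on
#' the catalog's mapped-gene symbol, case-insensitively.
#'
#' @param genes character vector of gene symbols.
#' @param bundle an [annotation_bundle()].
#' @param gwas_p_max association p-value ceiling.
#' @return named list gene -> character vector of matched traits (only
#'   matched genes appear).
#' @export
match_gwas_traits <- function(genes, bundle, gwas_p_max = 1e-6) {
  g <- bundle$gwas
  hit <- toupper(g$trait) %in% toupper(bundle$traits) & g$p < gwas_p_max
  g <- g[hit, , drop = FALSE]
  out <- lapply(genes, function(gene) {
    unique(g$trait[toupper(g$gene) == toupper(gene)])
  })
  names(out) <- genes
  out[vapply(out, length, 0L) > 0L]
}

#' Knowledge-driven candidate-gene prioritization cascade
#'
#' Round 1 keeps genes that are significant in the scan, expressed in the
#' kidney, and matched to a curated disease trait in the GWAS catalog.
#' Round 2 lifts the expression filter and adds significant trait-matched
#' genes not already selected. Include-list genes (the claudin family by
#' default) are added whenever significant, with their own provenance tag.
#'
#' @param scan gene-scan results data frame (columns `gene`, `p`).
#' @param bundle an [annotation_bundle()].
#' @param config a [prioritization_config()].
#' @param gm optional filtered `genotype_matrix` used to attach per-gene
#'   candidate variant ids.
#' @return data frame with columns `gene`, `p`, `provenance`
#'   (`round1` / `round2_no_expression` / `include_list`), `traits`
#'   (collapsed matched traits), `n_variants`, `variant_ids`.
#' @export
prioritize <- function(scan, bundle, config = prioritization_config(),
                       gm = NULL) {
  sig <- filter_significant(scan, config$alpha)
  matched <- match_gwas_traits(sig$gene, bundle, config$gwas_p_max)
  trait_genes <- names(matched)
  expressed <- filter_expression(trait_genes, bundle,
                                 config$require_both_evidence)
  round1 <- expressed
  round2 <- setdiff(trait_genes, round1)
  include <- setdiff(intersect(toupper(sig$gene), config$include_genes),
                     toupper(c(round1, round2)))
  include <- sig$gene[toupper(sig$gene) %in% include]

  build <- function(genes, tag) {
    if (length(genes) == 0L) return(NULL)
    data.frame(gene = genes,
               p = sig$p[match(genes, sig$gene)],
               provenance = tag,
               traits = vapply(genes, function(g) {
                 tr <- matched[[g]]
                 if (is.null(tr)) "" else paste(tr, collapse = "; ")
               }, ""),
               stringsAsFactors = FALSE)
  }
  out <- rbind(build(round1, "round1"),
               build(round2, "round2_no_expression"),
               build(include, "include_list"))
  if (is.null(out)) {
    out <- data.frame(gene = character(), p = numeric(),
                      provenance = character(), traits = character())
  }
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(gm)) {
    ids <- variant_ids(gm$variants)
    out$n_variants <- vapply(out$gene, function(g) {
      sum(gm$variants$gene == g)
    }, 0L)
    out$variant_ids <- vapply(out$gene, function(g) {
      paste(ids[gm$variants$gene == g], collapse = ",")
    }, "")
  }
  out
}
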