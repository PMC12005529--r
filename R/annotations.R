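#' Bundle of annotation tables driving the prioritization cascade
#'
#' @param expression data frame `gene`, `rna_evidence`, `protein_evidence`
#'   (logical flags for kidney expression evidence).
#' @param gwas data frame `variant_id`, `gene`, `trait`, `p` (GWAS-catalog
#'   style associations).
#' @param traits character vector of curated disease-related trait names.
#' @param eqtl data frame `variant_id`, `gene`, `tissue`, `p`.
#' @param gene_sets named list of character vectors (GMT-style gene sets).
#' @export
annotation_bundle <- function(expression, gwas, traits, eqtl, gene_sets) {
  stopifnot(all(c("gene", "rna_evidence", "protein_evidence") %in% names(expression)),
            all(c("variant_id", "gene", "trait", "p") %in% names(gwas)),
            all(c("variant_id", "gene", "tissue", "p") %in% names(eqtl)))
  if (any(!is.finite(gwas$p) | gwas$p <= 0 | gwas$p > 1)) {
    stop("GWAS association p-values must lie in (0, 1]")
  }
  if (any(!nzchar(traits))) stop("trait names must be non-empty")
  structure(list(expression = expression, gwas = gwas,
                 traits = unique(traits), eqtl = eqtl,
                 gene_sets = gene_sets),
            class = "annotation_bundle")
}

#' Read an annotation bundle from a directory of plain-text tables
#'
#' Expects `expression.tsv`, `gwas_catalog.tsv`, `traits.txt`, `eqtl.tsv`
#' and `gene_sets.gmt` as written by [write_cohort()].
#' @param dir directory path.
#' @export
read_annotation_bundle <- function(dir) {
  tsv <- function(f) utils::read.delim(file.path(dir, f), stringsAsFactors = FALSE)
  expression <- tsv("expression.tsv")
  expression$rna_evidence <- as.logical(expression$rna_evidence)
  expression$protein_evidence <- as.logical(expression$protein_evidence)
  annotation_bundle(
    expression = expression,
    gwas = tsv("gwas_catalog.tsv"),
    traits = readLines(file.path(dir, "traits.txt")),
    eqtl = tsv("eqtl.tsv"),
    gene_sets = read_gmt(file.path(dir, "gene_sets.gmt")))
}

#' Read gene sets from a GMT file
#' @param path GMT file (set name, description, tab-separated members).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
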