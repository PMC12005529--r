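#' Write a genotype matrix as an annotated multi-sample VCF
#'
#' Emits VCF 4.2 with a snpEff-dialect ANN INFO field
#' (`Allele|Annotation|Impact|Gene|...`) and per-sample `GT:DP`. Missing
#' dosages become `./.`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @export
write_annotated_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele | Annotation | Annotation_Impact | Gene_Name | Gene_ID | Feature_Type | Feature_ID | Transcript_BioType | Rank | HGVS.c'\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(gm$variants))) {
    v <- gm$variants[i, ]
    ann <- paste(v$alt, v$effect, v$impact, v$gene, v$gene, "transcript",
                 paste0(v$gene, ".1"), "protein_coding", "1/1", "c.1A>G",
                 sep = "|")
    d <- gm$dosage[i, ]
    gt <- ifelse(is.na(d), "./.", gt_codes[d + 1L])
    dp <- if (is.null(gm$depth)) rep(".", length(d)) else
      as.character(as.integer(gm$depth[i, ]))
    writeLines(paste(c(v$chrom, v$pos,
                       if (is.na(v$rsid)) "." else v$rsid,
                       v$ref, v$alt, ".", "PASS",
                       paste0("ANN=", ann), "GT:DP",
                       paste(gt, dp, sep = ":")), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a complete synthetic cohort to disk
#'
#' Emits every input the pipeline consumes: annotated VCF, phenotype and
#' eGFR TSVs, the annotation bundle (expression, GWAS-catalog-style, eQTL,
#' trait list, GMT gene sets), the reference-population genotype
#' distribution, and a ground-truth JSON of planted effects. Fixed seed in
#' the generating config implies byte-identical files.
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_annotated_vcf(cohort$genotypes, file.path(dir, "cohort.vcf"))
  tsv(cohort$phenotypes, "phenotypes.tsv")
  tsv(cohort$egfr, "egfr.tsv")
  tsv(cohort$bundle$expression, "expression.tsv")
  tsv(cohort$bundle$gwas, "gwas_catalog.tsv")
  writeLines(cohort$bundle$traits, file.path(dir, "traits.txt"))
  tsv(cohort$bundle$eqtl, "eqtl.tsv")
  write_gmt(cohort$bundle$gene_sets, file.path(dir, "gene_sets.gmt"))
  tsv(cohort$reference, "reference_population.tsv")
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, c("cohort.vcf", "phenotypes.tsv", "egfr.tsv",
                             "expression.tsv", "gwas_catalog.tsv",
                             "traits.txt", "eqtl.tsv", "gene_sets.gmt",
                             "reference_population.tsv", "ground_truth.json")))
}
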