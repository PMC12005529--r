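# shared fixtures built in code

## tiny hand-written annotated VCF: 3 biallelic records + 1 multi-allelic,
## 3 samples, GT:DP
write_tiny_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    paste(c("1", "100", "rs1", "A", "G", ".", "PASS",
            "ANN=G|missense_variant|MODERATE|GENE1|GENE1|transcript|t1|protein_coding|1/1|c.1A>G",
            "GT:DP", "0/1:30", "1/1:25", "0/0:40"), collapse = "\t"),
    paste(c("1", "200", "rs2", "C", "T", ".", "PASS",
            "ANN=T|synonymous_variant|LOW|GENE1|GENE1|transcript|t1|protein_coding|1/1|c.2C>T",
            "GT:DP", "0/0:22", "0/1:18", "./.:."), collapse = "\t"),
    paste(c("2", "300", "rs3", "G", "A", ".", "PASS",
            "ANN=A|missense_variant|MODERATE|GENE2|GENE2|transcript|t2|protein_coding|1/1|c.3G>A",
            "GT:DP", "0/0:7", "0/0:6", "0/1:5"), collapse = "\t"),
    paste(c("2", "400", "rs4", "T", "A,C", ".", "PASS",
            paste0("ANN=A|missense_variant|MODERATE|GENE3|GENE3|transcript|t3|protein_coding|1/1|c.4T>A,",
                   "C|stop_gained|HIGH|GENE3|GENE3|transcript|t3|protein_coding|1/1|c.4T>C"),
            "GT:DP", "1/2:33", "0/1:28", "2/2:31"), collapse = "\t"))
  writeLines(lines, path)
  path
}

## independent enumeration oracle for the two-sided 2x2 Fisher test:
## sum hypergeometric probabilities <= observed table's probability
fisher_2x2_oracle <- function(tab) {
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## small genotype matrix built directly
make_gm <- function(dosage, genes = NULL, depth = NULL,
                    impact = "MODERATE", effect = "missense_variant",
                    maf = NULL) {
  m <- nrow(dosage); n <- ncol(dosage)
  if (is.null(genes)) genes <- rep("GENE1", m)
  variants <- data.frame(
    chrom = rep("1", m), pos = seq_len(m) * 100L,
    ref = rep("A", m), alt = rep("G", m), rsid = sprintf("rs%d", seq_len(m)),
    gene = genes, effect = rep_len(effect, m),
    impact = rep_len(impact, m), stringsAsFactors = FALSE)
  if (!is.null(maf)) variants$maf <- maf
  if (is.null(depth)) depth <- matrix(30, m, n)
  genotype_matrix(variants, sprintf("P%02d", seq_len(n)), dosage, depth)
}

## phenotype calls table for a label vector
make_calls <- function(labels, ids = sprintf("P%02d", seq_along(labels))) {
  data.frame(patient_id = ids, group = labels, stringsAsFactors = FALSE)
}
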