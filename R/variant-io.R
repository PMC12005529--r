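#' Construct a genotype matrix object
#'
#' Container for a variants x samples ALT-dosage matrix plus variant
#' metadata. Dosages count ALT alleles (0/1/2), `NA` marks missing
#' genotypes.
#'
#' @param variants data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `rsid`, `gene`, `effect`, `impact`.
#' @param samples character vector of sample ids (column order of `dosage`).
#' @param dosage integer matrix, variants x samples.
#' @param depth optional numeric matrix of per-sample read depth, same shape.
#' @export
genotype_matrix <- function(variants, samples, dosage, depth = NULL) {
  variants <- as.data.frame(variants)
  needed <- c("chrom", "pos", "ref", "alt", "rsid", "gene", "effect", "impact")
  missing_cols <- setdiff(needed, names(variants))
  if (length(missing_cols)) {
    stop("variant table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != nrow(variants) || ncol(dosage) != length(samples)) {
    stop("dosage dimensions inconsistent with variants/samples")
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% 0:2)) stop("dosages must be 0, 1, 2 or NA")
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    stopifnot(all(dim(depth) == dim(dosage)))
  }
  ids <- variant_ids(variants)
  rownames(dosage) <- ids
  colnames(dosage) <- samples
  if (!is.null(depth)) dimnames(depth) <- dimnames(dosage)
  structure(list(variants = variants, samples = samples,
                 dosage = dosage, depth = depth),
            class = "genotype_matrix")
}

variant_ids <- function(variants) {
  ifelse(!is.na(variants$rsid) & nzchar(variants$rsid), variants$rsid,
         paste(variants$chrom, variants$pos, variants$ref, variants$alt,
               sep = ":"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$variants), "variants x",
      length(x$samples), "samples\n")
  cat("  impacts:", paste(names(table(x$variants$impact)),
                          table(x$variants$impact), collapse = ", "), "\n")
  cat("  missing dosages:", sum(is.na(x$dosage)), "\n")
  invisible(x)
}

#' Parse a snpEff-annotated multi-sample VCF
#'
#' Reads a VCF 4.2 file (via the vcfR package), splits multi-allelic sites
#' into biallelic records, maps GT to ALT-dosage (`./.` becomes missing),
#' extracts per-sample FORMAT/DP, and takes gene symbol, effect term and
#' impact class from the first ANN entry matching each alternate allele.
#' Records with malformed or absent ANN are kept with an unknown gene and a
#' warning (downstream filters remove them).
#'
#' @param path path to a VCF file with a GT FORMAT field.
#' @return a [genotype_matrix()].
#' @export
parse_annotated_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  if (nrow(v@fix) == 0L) {
    empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                        alt = character(), rsid = character(), gene = character(),
                        effect = character(), impact = character())
    return(genotype_matrix(empty, samples,
                           matrix(integer(), 0, length(samples)),
                           matrix(numeric(), 0, length(samples))))
  }
  fmt <- v@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) stop("VCF records lack the GT FORMAT field")
  gt <- vcfR::extract.gt(v, element = "GT")
  has_dp <- any(grepl("(^|:)DP(:|$)", fmt))
  dp <- if (has_dp) {
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  } else NULL

  info <- v@fix[, "INFO"]
  ann <- sub(".*(?:^|;)ANN=([^;]*).*", "\\1", info)
  ann[!grepl("(^|;)ANN=", info)] <- ""

  rows <- list(); dos <- list(); dpl <- list()
  n_bad_ann <- 0L
  for (i in seq_len(nrow(v@fix))) {
    alts <- strsplit(v@fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    ann_entries <- if (nzchar(ann[i])) strsplit(ann[i], ",", fixed = TRUE)[[1]] else character()
    gti <- gt[i, ]
    alleles <- strsplit(gsub("\\|", "/", gti), "/", fixed = FALSE)
    for (k in seq_along(alts)) {
      gene <- NA_character_; effect <- NA_character_; impact <- NA_character_
      hit <- NULL
      for (e in ann_entries) {
        f <- strsplit(e, "|", fixed = TRUE)[[1]]
        if (length(f) >= 4 && f[1] == alts[k]) { hit <- f; break }
      }
      if (is.null(hit) && length(ann_entries)) {
        f <- strsplit(ann_entries[1], "|", fixed = TRUE)[[1]]
        if (length(f) >= 4) hit <- f else n_bad_ann <- n_bad_ann + 1L
      }
      if (!is.null(hit)) {
        effect <- hit[2]; impact <- hit[3]; gene <- hit[4]
        if (!impact %in% c("HIGH", "MODERATE", "LOW", "MODIFIER")) {
          n_bad_ann <- n_bad_ann + 1L
          gene <- NA_character_; impact <- NA_character_
        }
      } else if (length(ann_entries) == 0L && nzchar(ann[i])) {
        n_bad_ann <- n_bad_ann + 1L
      }
      d <- vapply(alleles, function(a) {
        if (length(a) == 0L || anyNA(a) || any(a == ".")) return(NA_integer_)
        sum(a == as.character(k))
      }, integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = v@fix[i, "CHROM"], pos = as.integer(v@fix[i, "POS"]),
        ref = v@fix[i, "REF"], alt = alts[k],
        rsid = ifelse(is.na(v@fix[i, "ID"]) || v@fix[i, "ID"] == ".",
                      NA_character_, v@fix[i, "ID"]),
        gene = gene, effect = effect, impact = impact,
        stringsAsFactors = FALSE)
      dos[[length(dos) + 1L]] <- d
      dpl[[length(dpl) + 1L]] <- if (has_dp) dp[i, ] else rep(NA_real_, length(samples))
    }
  }
  if (n_bad_ann > 0L) {
    warning(n_bad_ann, " record(s) with malformed ANN kept with unknown gene")
  }
  variants <- do.call(rbind, rows)
  genotype_matrix(variants, samples,
                  do.call(rbind, dos),
                  do.call(rbind, dpl))
}

#' Default effect terms accepted by the impact filter
#' @export
default_allowed_effects <- function() {
  c("missense_variant", "splice_region_variant", "splice_donor_variant",
    "splice_acceptor_variant", "stop_lost", "stop_gained")
}

#' Impact and coverage filter
#'
#' Retains variants of predicted impact MODERATE or HIGH with read depth of
#' at least `min_depth` in at least `min_samples` samples. When an explicit
#' effect list is supplied it is enforced as a cross-check in addition to
#' the impact class. If the matrix carries no depth information the coverage
#' filter passes with a warning.
#'
#' @param gm a `genotype_matrix`.
#' @param allowed_effects optional character vector of effect terms.
#' @param min_depth minimum per-sample depth (default 10).
#' @param min_samples number of samples that must reach `min_depth`.
#' @return the filtered `genotype_matrix` (variant order preserved).
#' @export
filter_variants <- function(gm, allowed_effects = NULL, min_depth = 10,
                            min_samples = 1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (min_depth < 0) stop("min_depth must be non-negative")
  keep <- gm$variants$impact %in% c("MODERATE", "HIGH")
  if (!is.null(allowed_effects)) {
    keep <- keep & gm$variants$effect %in% allowed_effects
  }
  if (is.null(gm$depth) || all(is.na(gm$depth))) {
    warning("no depth information: coverage filter not applied")
  } else {
    cov_ok <- rowSums(gm$depth >= min_depth, na.rm = TRUE) >= min_samples
    keep <- keep & cov_ok
  }
  keep[is.na(keep)] <- FALSE
  genotype_matrix(gm$variants[keep, , drop = FALSE], gm$samples,
                  gm$dosage[keep, , drop = FALSE],
                  if (is.null(gm$depth)) NULL else gm$depth[keep, , drop = FALSE])
}

#' Group variants by annotated gene
#'
#' @param gm a (typically filtered) `genotype_matrix`.
#' @return list with `groups` (named list gene -> integer variant indices)
#'   and `unknown` (indices of variants with no usable gene symbol).
#' @export
group_by_gene <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gene <- gm$variants$gene
  known <- !is.na(gene) & nzchar(gene)
  groups <- split(which(known), gene[known])
  list(groups = groups, unknown = which(!known))
}
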