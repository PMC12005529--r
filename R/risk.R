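#' Reconstruct integer genotype counts from printed percentages
#'
#' Converts a (hom-alt, het, hom-ref) percentage triple and a group size
#' into integer counts by largest-remainder apportionment, guaranteeing the
#' counts sum exactly to `n`.
#'
#' @param pct numeric length-3 percentages (hom-alt, het, hom-ref).
#' @param n group size.
#' @return named integer vector `c(homalt, het, homref)`.
#' @export
reconstruct_counts <- function(pct, n) {
  stopifnot(length(pct) == 3L, all(pct >= 0), n >= 0)
  if (abs(sum(pct) - 100) > 3) {
    stop("percentages sum to ", sum(pct), "; outside 100 +/- 3")
  }
  raw <- n * pct / 100
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    rem <- raw - counts
    counts[order(rem, decreasing = TRUE)[seq_len(short)]] <-
      counts[order(rem, decreasing = TRUE)[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(counts), c("homalt", "het", "homref"))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact p-value summing hypergeometric probabilities of tables at most as
#' likely as the one observed (the convention of `stats::fisher.test`, used
#' internally). An empty row or column margin returns p = 1 with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts (rows =
#'   phenotype groups, columns = carrier vs reference genotype).
#' @return two-sided p-value.
#' @export
fisher_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("empty margin: Fisher p set to 1")
    return(1)
  }
  stats::fisher.test(table)$p.value
}

#' Odds ratio with Haldane-Anscombe correction
#'
#' `OR = (a d)/(b c)` with Wald 95% CI
#' `exp(log(OR) +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero (or `always = TRUE`), 0.5 is added to all four cells first so the
#' estimate and interval remain defined.
#'
#' @param table 2x2 count matrix `rbind(c(a, b), c(c, d))`.
#' @param always apply the 0.5 correction regardless of zeros.
#' @return list with `or`, `ci` (length-2), `correction_applied`.
#' @export
haldane_anscombe_or <- function(table, always = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0))
  if (all(table == 0)) stop("all cells are zero")
  corr <- always || any(table == 0)
  w <- table + if (corr) 0.5 else 0
  or <- (w[1, 1] * w[2, 2]) / (w[1, 2] * w[2, 1])
  se <- sqrt(sum(1 / w))
  list(or = or,
       ci = exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se),
       correction_applied = corr)
}

#' Per-variant genotype risk test
#'
#' Builds the 2x2 contingency table of FAST/noFAST against the mode's
#' carrier genotype (hom-alt or het) versus hom-ref (samples with the third
#' genotype are excluded), runs the Fisher exact test and the
#' Haldane-Anscombe odds ratio, and calls the risk allele from the OR
#' direction: ALT if OR > 1 (carrier genotype enriched in FAST), REF if
#' OR < 1.
#'
#' @param dosage per-sample ALT dosage vector (0/1/2, NA allowed:
#'   excluded).
#' @param groups per-sample group labels (`"FAST"`/`"noFAST"`).
#' @param mode `"homalt_vs_homref"` or `"het_vs_homref"`.
#' @return list with `mode`, `table`, `p`, `or`, `ci`,
#'   `correction_applied`, `risk_allele`, `associated_phenotype`.
#' @export
test_variant_risk <- function(dosage, groups,
                              mode = c("homalt_vs_homref", "het_vs_homref")) {
  mode <- match.arg(mode)
  stopifnot(length(dosage) == length(groups))
  if (!all(groups %in% c("FAST", "noFAST"))) {
    stop("groups must be FAST or noFAST for every sample")
  }
  carrier_dosage <- if (mode == "homalt_vs_homref") 2L else 1L
  keep <- !is.na(dosage) & dosage %in% c(carrier_dosage, 0L)
  d <- dosage[keep]; g <- groups[keep]
  tab <- rbind(FAST = c(sum(g == "FAST" & d == carrier_dosage),
                        sum(g == "FAST" & d == 0L)),
               noFAST = c(sum(g == "noFAST" & d == carrier_dosage),
                          sum(g == "noFAST" & d == 0L)))
  colnames(tab) <- c("carrier", "homref")
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    suppressWarnings(fisher_2x2(tab))
  } else fisher_2x2(tab)
  est <- haldane_anscombe_or(tab)
  risk_allele <- if (est$or > 1) "ALT" else if (est$or < 1) "REF" else NA_character_
  list(mode = mode, table = tab, p = p, or = est$or, ci = est$ci,
       correction_applied = est$correction_applied,
       risk_allele = risk_allele,
       associated_phenotype = if (is.na(risk_allele)) NA_character_
                              else if (est$or > 1) "FAST" else "noFAST")
}

#' Risk scan over all variants of a genotype matrix
#'
#' Runs [test_variant_risk()] in both genotype modes for every variant and
#' pools all variant x mode tests into one Benjamini-Hochberg family.
#'
#' @param gm a `genotype_matrix` (typically restricted to prioritized
#'   genes).
#' @param calls data frame with `patient_id` and `group` columns.
#' @param modes which genotype contrasts to run.
#' @return data frame: `variant_id`, `gene`, `mode`, counts `a`..`d`, `p`,
#'   `q`, `or`, `ci_low`, `ci_high`, `correction_applied`, `risk_allele`,
#'   `associated_phenotype`.
#' @export
risk_variant_scan <- function(gm, calls,
                              modes = c("homalt_vs_homref", "het_vs_homref")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!setequal(calls$patient_id, gm$samples)) {
    stop("sample-id mismatch between genotype matrix and phenotype calls")
  }
  groups <- calls$group[match(gm$samples, calls$patient_id)]
  ids <- variant_ids(gm$variants)
  rows <- list()
  for (i in seq_len(nrow(gm$variants))) {
    for (mode in modes) {
      r <- test_variant_risk(gm$dosage[i, ], groups, mode)
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = ids[i], gene = gm$variants$gene[i], mode = mode,
        a = r$table[1, 1], b = r$table[1, 2],
        c = r$table[2, 1], d = r$table[2, 2],
        p = r$p, or = r$or, ci_low = r$ci[1], ci_high = r$ci[2],
        correction_applied = r$correction_applied,
        risk_allele = r$risk_allele,
        associated_phenotype = r$associated_phenotype,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- adjust_pvalues(out$p)
  out[, c("variant_id", "gene", "mode", "a", "b", "c", "d", "p", "q", "or",
          "ci_low", "ci_high", "correction_applied", "risk_allele",
          "associated_phenotype")]
}

#' Select significant risk variants
#'
#' Retains tests with Fisher p below `p_max`, BH q below `q_max`, and an
#' odds ratio different from 1.
#'
#' @param results data frame from [risk_variant_scan()] (must share one BH
#'   family in `q`).
#' @param p_max,q_max selection thresholds (defaults 0.05 and 0.15).
#' @return the selected subset, ordered by mode then p.
#' @export
select_risk_variants <- function(results, p_max = 0.05, q_max = 0.15) {
  sel <- results[results$p < p_max & results$q < q_max & results$or != 1, ,
                 drop = FALSE]
  sel <- sel[order(sel$mode, sel$p), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Exact test for equality of genotype distributions across groups
#'
#' Fisher exact test on the groups x genotypes (hom-alt/het/hom-ref) table.
#' Full conditional enumeration is used when feasible; otherwise the
#' p-value is estimated by Monte-Carlo sampling of tables with the observed
#' margins (1e5 tables) and the standard error is reported.
#'
#' @param distributions list of per-group counts; each element a named
#'   numeric vector `c(homalt, het, homref)` (group names taken from list
#'   names).
#' @return list with `p`, `method` (`"enumeration"`/`"monte_carlo"`) and
#'   `se` (0 for enumeration).
#' @export
genotype_distribution_test <- function(distributions) {
  stopifnot(length(distributions) >= 2L)
  tab <- do.call(rbind, distributions)
  if (all(tab == 0)) stop("all-zero table")
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L || nrow(tab[rowSums(tab) > 0, , drop = FALSE]) < 2L) {
    return(list(p = 1, method = "degenerate", se = 0))
  }
  B <- 1e5
  if (sum(tab) <= 300) {
    res <- tryCatch(stats::fisher.test(tab, workspace = 2e7),
                    error = function(e) NULL)
    if (!is.null(res)) {
      return(list(p = res$p.value, method = "enumeration", se = 0))
    }
  }
  res <- stats::fisher.test(tab, simulate.p.value = TRUE, B = B)
  p <- res$p.value
  list(p = p, method = "monte_carlo", se = sqrt(p * (1 - p) / B))
}

#' Join selected risk variants against an eQTL table
#'
#' @param selected data frame with a `variant_id` column.
#' @param bundle an [annotation_bundle()].
#' @param threshold eQTL significance threshold (default 1e-6).
#' @return `selected` with added `eqtl_tissue`, `eqtl_p`,
#'   `eqtl_significant` columns; variants without a record get
#'   `"no record"` and `NA`.
#' @export
annotate_eqtl <- function(selected, bundle, threshold = 1e-6) {
  idx <- match(selected$variant_id, bundle$eqtl$variant_id)
  selected$eqtl_tissue <- ifelse(is.na(idx), "no record",
                                 bundle$eqtl$tissue[idx])
  selected$eqtl_p <- bundle$eqtl$p[idx]
  selected$eqtl_significant <- !is.na(idx) & bundle$eqtl$p[idx] < threshold
  selected
}

#' Per-patient risk-allele burden
#'
#' Counts, for every patient, the selected risk variants whose risk
#' genotype the patient carries: dosage 2 for ALT-risk hom-alt mode tests,
#' dosage 0 for REF-risk hom-alt mode tests, dosage 1 for het-mode tests.
#'
#' @param gm a `genotype_matrix` containing the selected variants.
#' @param selected data frame from [select_risk_variants()].
#' @param calls data frame with `patient_id` and `group`.
#' @param range burden interval for the group summary (default `c(9, 15)`).
#' @return list with `per_patient` (patient_id, group, n_risk) and
#'   `summary` (per-group min, max, and fraction of patients inside
#'   `range`).
#' @export
risk_allele_burden <- function(gm, selected, calls, range = c(9, 15)) {
  if (nrow(selected) == 0L) stop("no selected risk variants")
  ids <- variant_ids(gm$variants)
  groups <- calls$group[match(gm$samples, calls$patient_id)]
  counts <- integer(length(gm$samples))
  for (k in seq_len(nrow(selected))) {
    i <- match(selected$variant_id[k], ids)
    if (is.na(i)) stop("selected variant absent from matrix: ",
                       selected$variant_id[k])
    d <- gm$dosage[i, ]
    carrier <- if (selected$mode[k] == "het_vs_homref") {
      d == 1L
    } else if (identical(selected$risk_allele[k], "REF")) {
      d == 0L
    } else {
      d == 2L
    }
    counts <- counts + as.integer(carrier %in% TRUE)
  }
  per_patient <- data.frame(patient_id = gm$samples, group = groups,
                            n_risk = counts, stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(split(per_patient, per_patient$group),
    function(d) data.frame(group = d$group[1], n = nrow(d),
                           min = min(d$n_risk), max = max(d$n_risk),
                           frac_in_range = mean(d$n_risk >= range[1] &
                                                d$n_risk <= range[2]))))
  rownames(summary) <- NULL
  list(per_patient = per_patient, summary = summary, range = range)
}
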