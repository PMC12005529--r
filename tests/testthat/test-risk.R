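test_that("percentage triples reconstruct to exact integer counts", {
  # printed genotype percentages for a 6-patient and a 24-patient group
  expect_equal(reconstruct_counts(c(84, 0, 16), 6),
               c(homalt = 5L, het = 0L, homref = 1L))
  expect_equal(reconstruct_counts(c(0, 54, 46), 24),
               c(homalt = 0L, het = 13L, homref = 11L))
  expect_equal(reconstruct_counts(c(100, 0, 0), 10),
               c(homalt = 10L, het = 0L, homref = 0L))
  expect_error(reconstruct_counts(c(50, 30, 10), 10), "outside")
})

test_that("count reconstruction round-trips integer percentages", {
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(1:50, 1)
    counts <- as.vector(rmultinom(1, n, c(0.2, 0.5, 0.3)))
    pct <- round(100 * counts / n)
    back <- reconstruct_counts(pct, n)
    expect_equal(sum(back), n)
    # largest remainder recovers the source counts up to rounding ties
    expect_lte(max(abs(back - counts)), 1)
  }
})

test_that("two-sided Fisher p matches exhaustive hypergeometric enumeration", {
  t_nfu1 <- rbind(c(5, 1), c(0, 11))
  t_cd86 <- rbind(c(2, 1), c(1, 16))
  expect_equal(fisher_2x2(t_nfu1), 9.70e-4, tolerance = 1e-3)
  expect_equal(fisher_2x2(t_cd86), 0.0456, tolerance = 1e-3)
  expect_equal(fisher_2x2(t_nfu1), fisher_2x2_oracle(t_nfu1), tolerance = 1e-10)
  expect_equal(fisher_2x2(t_cd86), fisher_2x2_oracle(t_cd86), tolerance = 1e-10)
  expect_equal(fisher_2x2(rbind(c(3, 3), c(3, 3))), 1)
  expect_warning(p <- fisher_2x2(rbind(c(0, 0), c(2, 3))), "margin")
  expect_equal(p, 1)
})

test_that("Fisher p equals the enumeration oracle on all small tables", {
  for (a in 0:4) for (b in 0:4) for (c in 0:3) for (d in 0:3) {
    tab <- rbind(c(a, b), c(c, d))
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_2x2(tab), fisher_2x2_oracle(tab), tolerance = 1e-9)
  }
})

test_that("Haldane-Anscombe odds ratios follow the corrected formula", {
  r <- haldane_anscombe_or(rbind(c(5, 1), c(0, 11)))
  expect_true(r$correction_applied)
  expect_equal(r$or, (5.5 * 11.5) / (1.5 * 0.5), tolerance = 1e-12)
  expect_equal(r$or, 84.33, tolerance = 1e-4)
  r2 <- haldane_anscombe_or(rbind(c(2, 1), c(1, 16)))
  expect_false(r2$correction_applied)
  expect_equal(r2$or, 32)
  expect_true(r2$ci[1] <= r2$or && r2$or <= r2$ci[2])
  expect_equal(haldane_anscombe_or(rbind(c(1, 1), c(1, 1)))$or, 1)
  expect_error(haldane_anscombe_or(matrix(0, 2, 2)), "zero")
})

test_that("swapping table rows inverts the OR and keeps p", {
  set.seed(9)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 5), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    sw <- tab[2:1, ]
    expect_equal(fisher_2x2(tab), fisher_2x2(sw), tolerance = 1e-12)
    expect_equal(haldane_anscombe_or(tab)$or,
                 1 / haldane_anscombe_or(sw)$or, tolerance = 1e-9)
  }
})

test_that("variant risk test calls direction and phenotype", {
  # severe-group enrichment of the hom-alt genotype (strong recessive signal)
  dos <- c(rep(2L, 5), 0L, rep(1L, 13), rep(0L, 11))
  grp <- c(rep("FAST", 6), rep("noFAST", 24))
  r <- test_variant_risk(dos, grp, "homalt_vs_homref")
  expect_equal(unname(r$table), rbind(c(5, 1), c(0, 11)))
  expect_equal(r$risk_allele, "ALT")
  expect_equal(r$associated_phenotype, "FAST")
  # hom-alt enriched in the mild group flips the risk allele to REF
  r2 <- test_variant_risk(2L - dos, grp, "homalt_vs_homref")
  expect_equal(r2$risk_allele, "REF")
  expect_equal(r2$associated_phenotype, "noFAST")
  # balanced variant: OR 1, not significant
  bal <- rep(c(2L, 0L), 15)
  r3 <- suppressWarnings(test_variant_risk(bal, grp, "homalt_vs_homref"))
  expect_gt(r3$p, 0.5)
})

test_that("risk selection applies p, q and OR criteria", {
  res <- data.frame(variant_id = c("v1", "v2", "v3"),
                    mode = "homalt_vs_homref",
                    p = c(0.001, 0.04, 0.5), q = c(0.01, 0.30, 0.9),
                    or = c(84, 3, 1))
  sel <- select_risk_variants(res)
  expect_equal(sel$variant_id, "v1")
})

test_that("planted extreme variants survive selection among nulls", {
  set.seed(21)
  grp <- c(rep("FAST", 6), rep("noFAST", 24))
  n <- 30
  # 5 planted with the strong recessive pattern, 95 null variants
  planted <- t(replicate(5, c(rep(2L, 5), 0L, rep(1L, 13), rep(0L, 11))))
  null <- matrix(rbinom(95 * n, 2, 0.25), 95, n)
  gm <- make_gm(rbind(planted, null),
                genes = sprintf("G%03d", 1:100))
  res <- risk_variant_scan(gm, make_calls(grp))
  sel <- select_risk_variants(res)
  planted_ids <- sprintf("rs%d", 1:5)
  hom <- sel[sel$mode == "homalt_vs_homref", ]
  expect_true(all(planted_ids %in% hom$variant_id))
})

test_that("genotype distribution test detects divergent groups", {
  same <- list(FAST = c(homalt = 3, het = 2, homref = 1),
               noFAST = c(homalt = 3, het = 2, homref = 1))
  expect_equal(genotype_distribution_test(same)$p, 1)
  div <- list(FAST = c(homalt = 5, het = 0, homref = 1),
              noFAST = c(homalt = 0, het = 13, homref = 11))
  r <- genotype_distribution_test(div)
  expect_lt(r$p, 0.001)
  expect_equal(r$method, "enumeration")
  expect_error(genotype_distribution_test(list(a = c(0, 0, 0), b = c(0, 0, 0))),
               "zero")
})

test_that("enumeration and Monte-Carlo genotype tests agree", {
  set.seed(31)
  for (rep in 1:5) {
    tab <- list(g1 = rpois(3, 4) + 1, g2 = rpois(3, 4) + 1, g3 = rpois(3, 4) + 1)
    exact <- genotype_distribution_test(tab)
    mc <- stats::fisher.test(do.call(rbind, tab), simulate.p.value = TRUE,
                             B = 1e5)$p.value
    se <- sqrt(mc * (1 - mc) / 1e5)
    expect_lt(abs(exact$p - mc), 3 * se + 1e-3)
  }
})

test_that("eQTL annotation joins and applies the threshold", {
  bundle <- annotation_bundle(
    expression = data.frame(gene = "NFU1", rna_evidence = TRUE,
                            protein_evidence = TRUE),
    gwas = data.frame(variant_id = "x", gene = "NFU1", trait = "eGFR", p = 1e-9),
    traits = "eGFR",
    eqtl = data.frame(variant_id = "rs4453725", gene = "NFU1",
                      tissue = "kidney tubule", p = 2.14e-12),
    gene_sets = list(s = "NFU1"))
  sel <- data.frame(variant_id = c("rs4453725", "rs999"))
  out <- annotate_eqtl(sel, bundle)
  expect_true(out$eqtl_significant[1])
  expect_equal(out$eqtl_tissue[2], "no record")
  expect_false(out$eqtl_significant[2])
  out20 <- annotate_eqtl(sel, bundle, threshold = 1e-20)
  expect_false(out20$eqtl_significant[1])
})

test_that("risk-allele burden counts carriers per mode and summarizes", {
  # 3 variants: ALT-hom risk, REF-hom risk, het risk
  dosage <- rbind(c(2L, 0L, 1L),
                  c(0L, 2L, 0L),
                  c(1L, 1L, 0L))
  gm <- make_gm(dosage, genes = c("G1", "G2", "G3"))
  calls <- make_calls(c("FAST", "FAST", "noFAST"), gm$samples)
  selected <- data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    mode = c("homalt_vs_homref", "homalt_vs_homref", "het_vs_homref"),
    risk_allele = c("ALT", "REF", "ALT"), stringsAsFactors = FALSE)
  b <- risk_allele_burden(gm, selected, calls, range = c(2, 3))
  # P03 carries the REF-risk hom-ref genotype of rs2
  expect_equal(b$per_patient$n_risk, c(3L, 1L, 1L))
  s <- b$summary[b$summary$group == "FAST", ]
  expect_equal(s$max, 3)
  expect_equal(s$frac_in_range, 0.5)
})

test_that("burden group summary mirrors the carriage-fraction form", {
  counts <- c(9L, 10L, 12L, 15L, 4L, 2L)
  gm <- make_gm(matrix(rep(2L, 6 * 15), 15, 6, byrow = TRUE) *
                  t(sapply(1:15, function(v) as.integer(counts >= v))),
                genes = sprintf("G%d", 1:15))
  selected <- data.frame(variant_id = sprintf("rs%d", 1:15),
                         mode = "homalt_vs_homref", risk_allele = "ALT",
                         stringsAsFactors = FALSE)
  calls <- make_calls(rep("FAST", 6), gm$samples)
  b <- risk_allele_burden(gm, selected, calls, range = c(9, 15))
  expect_equal(sort(b$per_patient$n_risk), sort(counts))
  expect_equal(b$summary$frac_in_range, 4 / 6)
  expect_equal(round(100 * b$summary$frac_in_range), 67)
})
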