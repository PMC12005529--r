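#' Configuration of the synthetic extreme-phenotype cohort
#'
#' Defines the study conditions emulated by the generator: a small binary
#' extreme-phenotype cohort (6 fast progressors vs 24 non-fast by default,
#' matching a rare-disease discovery design), Hardy-Weinberg genotypes over
#' a rare-shifted MAF spectrum, and planted modifier variants acting on the
#' phenotype through a logistic dosage model or an explicit per-genotype
#' penetrance.
#'
#' @param n_fast,n_nofast cohort group sizes (each at least 1).
#' @param n_genes number of simulated genes.
#' @param variants_per_gene integer range `c(min, max)` of variants drawn
#'   per gene.
#' @param maf_spectrum list describing the MAF distribution: `dist`
#'   (`"beta"` or `"uniform"`), shape/range parameters, and `min`/`max`
#'   truncation bounds inside `(0, 0.5]`.
#' @param planted_effects list of planted modifier variants; each element a
#'   list with `gene` (index or name), `variant` (index within the gene,
#'   default 1), optionally `maf`, and either `beta` (log-odds per ALT
#'   dosage) or `penetrance` (length-3 probability of FAST for dosages
#'   0/1/2).
#' @param baseline_logit intercept of the phenotype model; defaults to
#'   `qlogis(n_fast / (n_fast + n_nofast))`.
#' @param missing_rate fraction of dosages set to missing (default 0).
#' @param prop_low_impact fraction of non-planted variants annotated with
#'   LOW impact (exercises the impact filter).
#' @param seed integer RNG seed; a fixed seed gives byte-identical cohorts.
#' @export
cohort_sim_config <- function(n_fast = 6, n_nofast = 24, n_genes = 50,
                              variants_per_gene = c(1, 5),
                              maf_spectrum = list(dist = "beta", shape1 = 1,
                                                  shape2 = 5, min = 0.01,
                                                  max = 0.5),
                              planted_effects = list(),
                              baseline_logit = NULL,
                              missing_rate = 0,
                              prop_low_impact = 0.1,
                              seed = 1L) {
  stopifnot(n_fast >= 1, n_nofast >= 1, n_genes >= 1,
            length(variants_per_gene) == 2L,
            variants_per_gene[1] >= 1,
            variants_per_gene[2] >= variants_per_gene[1],
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(maf_spectrum$min) &&
      (maf_spectrum$min <= 0 || maf_spectrum$max > 0.5)) {
    stop("maf_spectrum truncation bounds must lie in (0, 0.5]")
  }
  for (pe in planted_effects) {
    if (is.null(pe$gene)) stop("each planted effect needs a gene")
    if (is.null(pe$beta) && is.null(pe$penetrance)) {
      stop("each planted effect needs beta or penetrance")
    }
    if (!is.null(pe$maf) &&
        (!is.finite(pe$maf) || pe$maf <= 0 || pe$maf > 0.5)) {
      stop("planted MAF out of (0, 0.5] for gene ", pe$gene)
    }
  }
  if (is.null(baseline_logit)) {
    baseline_logit <- stats::qlogis(n_fast / (n_fast + n_nofast))
  }
  structure(list(n_fast = n_fast, n_nofast = n_nofast, n_genes = n_genes,
                 variants_per_gene = variants_per_gene,
                 maf_spectrum = maf_spectrum,
                 planted_effects = planted_effects,
                 baseline_logit = baseline_logit,
                 missing_rate = missing_rate,
                 prop_low_impact = prop_low_impact,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Configuration of synthetic eGFR trajectories
#'
#' Class-conditional annual-slope distributions; fast progressors lose at
#' least 10 mL/min/1.73m2 per year by construction, moderate progressors
#' decline without reaching that cutoff, slow progressors are stable.
#'
#' @param slope_mean,slope_sd named vectors (`fast`, `moderate`, `slow`) of
#'   slope distributions in mL/min/1.73m2/yr (negative = decline).
#' @param baseline_mean,baseline_sd baseline eGFR distribution.
#' @param noise_sd measurement noise standard deviation (>= 0).
#' @param visits_range integer range of measurement counts per patient.
#' @param span_years follow-up span.
#' @param egfr_floor smallest representable eGFR.
#' @export
trajectory_sim_config <- function(slope_mean = c(fast = -15, moderate = -5, slow = 0),
                                  slope_sd = c(fast = 3, moderate = 2, slow = 0.4),
                                  baseline_mean = 90, baseline_sd = 15,
                                  noise_sd = 5, visits_range = c(4, 8),
                                  span_years = 5, egfr_floor = 1) {
  stopifnot(noise_sd >= 0, span_years > 0, visits_range[1] >= 1,
            -slope_mean[["fast"]] >= 10, abs(slope_mean[["slow"]]) <= 1)
  structure(list(slope_mean = slope_mean, slope_sd = slope_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, visits_range = visits_range,
                 span_years = span_years, egfr_floor = egfr_floor),
            class = "trajectory_sim_config")
}

## sample() that treats a length-1 vector as a single choice
sample_from <- function(x, size = 1, replace = FALSE) {
  if (length(x) == 1L) return(rep(x, size))
  sample(x, size, replace = replace)
}

## deterministic variant panel for a config (genes, positions, MAFs,
## effects/impacts); draws from the current RNG stream
draw_variant_panel <- function(config) {
  genes <- sprintf("GENE%03d", seq_len(config$n_genes))
  nv <- sample_from(seq(config$variants_per_gene[1], config$variants_per_gene[2]),
                    config$n_genes, replace = TRUE)
  gene_of <- rep(genes, nv)
  m <- length(gene_of)
  ms <- config$maf_spectrum
  maf <- switch(ms$dist,
    beta = 0.5 * stats::rbeta(m, ms$shape1, ms$shape2),
    uniform = stats::runif(m, ms$min, ms$max),
    stop("unknown maf_spectrum dist: ", ms$dist))
  maf <- pmin(pmax(maf, ms$min), ms$max)
  low <- stats::runif(m) < config$prop_low_impact
  effect <- ifelse(low, "synonymous_variant",
                   sample(default_allowed_effects(), m, replace = TRUE,
                          prob = c(0.8, 0.05, 0.04, 0.04, 0.02, 0.05)))
  impact <- ifelse(low, "LOW",
                   ifelse(effect %in% c("stop_gained", "stop_lost",
                                        "splice_donor_variant",
                                        "splice_acceptor_variant"),
                          "HIGH", "MODERATE"))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  panel <- data.frame(
    chrom = as.character(1 + (match(gene_of, genes) - 1) %% 22),
    pos = 10000L + 100L * seq_len(m),
    ref = ref, alt = alt,
    rsid = sprintf("rs9%06d", seq_len(m)),
    gene = gene_of, effect = effect, impact = impact,
    maf = maf, planted = FALSE, stringsAsFactors = FALSE)

  for (pe in config$planted_effects) {
    g <- if (is.numeric(pe$gene)) genes[pe$gene] else pe$gene
    idx <- which(panel$gene == g)
    if (length(idx) == 0L) stop("planted gene not in panel: ", g)
    vi <- if (is.null(pe$variant)) 1L else as.integer(pe$variant)
    if (vi < 1L || vi > length(idx)) {
      stop("planted variant index out of range for gene ", g)
    }
    j <- idx[vi]
    panel$planted[j] <- TRUE
    panel$effect[j] <- "missense_variant"
    panel$impact[j] <- "MODERATE"
    if (!is.null(pe$maf)) panel$maf[j] <- pe$maf
  }
  panel
}

draw_dosages <- function(panel, n) {
  m <- nrow(panel)
  matrix(stats::rbinom(m * n, 2L, rep(panel$maf, times = n)), nrow = m)
}

draw_depth <- function(m, n) {
  matrix(stats::rnbinom(m * n, mu = 97, size = 20) + 1, nrow = m)
}

#' Simulate Hardy-Weinberg genotypes for a synthetic cohort
#'
#' Draws a variant panel (genes, MAFs, annotations, read depths) and
#' per-variant dosages under Hardy-Weinberg equilibrium. Deterministic
#' under the config seed.
#'
#' @param config a [cohort_sim_config()].
#' @param n_samples number of samples (defaults to `n_fast + n_nofast`).
#' @return a [genotype_matrix()] whose variant table additionally carries
#'   `maf` (true simulated MAF) and `planted`.
#' @export
simulate_genotypes <- function(config, n_samples = NULL) {
  stopifnot(inherits(config, "cohort_sim_config"))
  if (is.null(n_samples)) n_samples <- config$n_fast + config$n_nofast
  set.seed(config$seed)
  panel <- draw_variant_panel(config)
  D <- draw_dosages(panel, n_samples)
  depth <- draw_depth(nrow(panel), n_samples)
  if (config$missing_rate > 0) {
    D[stats::runif(length(D)) < config$missing_rate] <- NA_integer_
  }
  genotype_matrix(panel, sprintf("P%03d", seq_len(n_samples)), D, depth)
}

## per-sample linear predictor of the phenotype model
phenotype_eta <- function(D, panel, config) {
  eta <- rep(config$baseline_logit, ncol(D))
  for (pe in config$planted_effects) {
    g <- if (is.numeric(pe$gene)) sprintf("GENE%03d", pe$gene) else pe$gene
    idx <- which(panel$gene == g)
    vi <- if (is.null(pe$variant)) 1L else as.integer(pe$variant)
    if (vi < 1L || vi > length(idx)) {
      stop("planted variant index out of range for gene ", g)
    }
    d <- D[idx[vi], ]
    if (anyNA(d)) d[is.na(d)] <- 0L
    if (!is.null(pe$beta)) {
      eta <- eta + pe$beta * d
    } else {
      eta <- eta + stats::qlogis(pe$penetrance[d + 1L]) - config$baseline_logit
    }
  }
  eta
}

#' Plant modifier phenotypes on a simulated genotype matrix
#'
#' Samples FAST/noFAST labels from the logistic dosage model
#' `P(FAST | dosages) = plogis(baseline_logit + sum(effect * dosage))`;
#' penetrance-type effects substitute the per-genotype probability directly.
#'
#' @param gm genotype matrix from [simulate_genotypes()].
#' @param config the same [cohort_sim_config()].
#' @return list with `labels` (`"FAST"`/`"noFAST"`), `prob` (latent
#'   P(FAST)), and `ground_truth` (data frame of planted variants).
#' @export
plant_modifier_phenotypes <- function(gm, config) {
  stopifnot(inherits(gm, "genotype_matrix"))
  prob <- stats::plogis(phenotype_eta(gm$dosage, gm$variants, config))
  labels <- ifelse(stats::runif(length(prob)) < prob, "FAST", "noFAST")
  list(labels = labels, prob = prob, ground_truth = ground_truth_table(gm, config))
}

ground_truth_table <- function(gm, config) {
  if (length(config$planted_effects) == 0L) {
    return(data.frame(gene = character(), variant_id = character(),
                      maf = numeric(), effect_type = character(),
                      effect = character()))
  }
  rows <- lapply(config$planted_effects, function(pe) {
    g <- if (is.numeric(pe$gene)) sprintf("GENE%03d", pe$gene) else pe$gene
    idx <- which(gm$variants$gene == g)
    vi <- if (is.null(pe$variant)) 1L else as.integer(pe$variant)
    j <- idx[vi]
    data.frame(gene = g, variant_id = variant_ids(gm$variants)[j],
               maf = gm$variants$maf[j],
               effect_type = if (!is.null(pe$beta)) "log_odds_per_dosage" else "penetrance",
               effect = if (!is.null(pe$beta)) as.character(pe$beta) else
                 paste(pe$penetrance, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate one patient's eGFR trajectory
#'
#' Draws an annual slope from the class-conditional distribution (fast
#' slopes truncated to a decline of at least 10, moderate to (1, 10),
#' slow to at most 1), a baseline, measurement times over the follow-up
#' span, and Gaussian measurement noise. eGFR is floored at a small
#' positive value. With `noise_sd = 0` the least-squares slope of the
#' series equals the drawn slope exactly.
#'
#' @param class `"fast"`, `"moderate"` or `"slow"`.
#' @param config a [trajectory_sim_config()].
#' @param visits optional fixed number of visits (>= 1).
#' @return list with `times`, `values`, `true_slope`, `baseline`, `class`.
#' @export
simulate_egfr_series <- function(class, config = trajectory_sim_config(),
                                 visits = NULL) {
  class <- match.arg(class, c("fast", "moderate", "slow"))
  if (is.null(visits)) {
    visits <- sample_from(seq(config$visits_range[1], config$visits_range[2]))
  }
  if (visits < 1) stop("visits must be at least 1")
  draw_slope <- function() {
    stats::rnorm(1, config$slope_mean[[class]], config$slope_sd[[class]])
  }
  ok <- switch(class,
    fast = function(s) -s >= 10,
    moderate = function(s) -s < 10 && -s > 1,
    slow = function(s) -s <= 1)
  slope <- draw_slope()
  tries <- 0L
  while (!ok(slope) && tries < 1000L) { slope <- draw_slope(); tries <- tries + 1L }
  baseline <- max(stats::rnorm(1, config$baseline_mean, config$baseline_sd), 30)
  times <- if (visits == 1L) 0 else
    c(0, sort(stats::runif(visits - 1L, 0.2, config$span_years)))
  ## follow-up is censored once the underlying trajectory reaches the
  ## floor (kidney failure): later visits do not exist
  keep <- baseline + slope * times >= config$egfr_floor
  keep[seq_len(min(length(times), 2L))] <- TRUE
  times <- times[keep]
  values <- baseline + slope * times +
    if (config$noise_sd > 0) stats::rnorm(length(times), 0, config$noise_sd) else 0
  values <- pmax(values, config$egfr_floor)
  list(times = times, values = values, true_slope = slope,
       baseline = baseline, class = class)
}

#' Simulate a complete extreme-phenotype cohort with known ground truth
#'
#' Composes the generator stages into a full synthetic study: genotypes and
#' phenotype labels are drawn jointly from the logistic dosage model by
#' case-control (rejection) sampling until exactly `n_fast` FAST and
#' `n_nofast` noFAST patients are collected, eGFR trajectories are
#' simulated per patient consistent with the group label, and the
#' annotation tables driving the prioritization cascade (kidney expression,
#' GWAS-catalog-style associations, eQTLs, gene sets, reference-population
#' genotype distributions) are generated so that planted genes are
#' discoverable.
#'
#' @param config a [cohort_sim_config()].
#' @param traj a [trajectory_sim_config()].
#' @param n_reference size of the synthetic reference population used for
#'   the genotype-distribution table (default 73).
#' @return a list of class `synthetic_cohort` with elements `genotypes`,
#'   `phenotypes`, `egfr`, `bundle`, `reference`, `ground_truth`, `config`.
#' @export
simulate_cohort <- function(config, traj = trajectory_sim_config(),
                            n_reference = 73L) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  panel <- draw_variant_panel(config)
  n_need <- c(FAST = config$n_fast, noFAST = config$n_nofast)
  cols <- list(FAST = NULL, noFAST = NULL)
  guard <- 0L
  while (any(vapply(cols, function(x) if (is.null(x)) 0L else ncol(x),
                    0L) < n_need) && guard < 200L) {
    guard <- guard + 1L
    B <- max(4L * sum(n_need), 200L)
    D <- draw_dosages(panel, B)
    prob <- stats::plogis(phenotype_eta(D, panel, config))
    lab <- ifelse(stats::runif(B) < prob, "FAST", "noFAST")
    for (g in c("FAST", "noFAST")) {
      need <- n_need[[g]] - (if (is.null(cols[[g]])) 0L else ncol(cols[[g]]))
      if (need > 0L) {
        take <- which(lab == g)[seq_len(min(need, sum(lab == g)))]
        cols[[g]] <- cbind(cols[[g]], D[, take, drop = FALSE])
      }
    }
  }
  if (any(vapply(cols, ncol, 0L) < n_need)) {
    stop("could not fill group quotas; phenotype model too extreme")
  }
  D <- cbind(cols$FAST, cols$noFAST)
  labels <- rep(c("FAST", "noFAST"), n_need)
  ord <- sample(ncol(D))           # shuffle so sample order carries no signal
  D <- D[, ord, drop = FALSE]
  labels <- labels[ord]
  n <- ncol(D)
  if (config$missing_rate > 0) {
    D[stats::runif(length(D)) < config$missing_rate] <- NA_integer_
  }
  gm <- genotype_matrix(panel, sprintf("P%03d", seq_len(n)), D,
                        draw_depth(nrow(panel), n))

  cls <- ifelse(labels == "FAST", "fast",
                sample(c("moderate", "slow"), n, replace = TRUE))
  series <- lapply(cls, function(cl) simulate_egfr_series(cl, traj))
  egfr <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(patient_id = gm$samples[i],
               time = round(series[[i]]$times, 4),
               egfr = round(series[[i]]$values, 2))
  }))
  phenotypes <- data.frame(patient_id = gm$samples, group = labels,
                           true_class = cls,
                           true_slope = vapply(series, `[[`, 0, "true_slope"),
                           stringsAsFactors = FALSE)

  bundle <- simulate_annotation_bundle(gm, config)
  reference <- simulate_reference_distribution(gm, n_reference)
  gt <- list(planted = ground_truth_table(gm, config),
             seed = config$seed,
             n_fast = config$n_fast, n_nofast = config$n_nofast)
  structure(list(genotypes = gm, phenotypes = phenotypes, egfr = egfr,
                 bundle = bundle, reference = reference, ground_truth = gt,
                 config = config),
            class = "synthetic_cohort")
}

## annotation tables with planted genes discoverable through the cascade
simulate_annotation_bundle <- function(gm, config) {
  genes <- unique(gm$variants$gene)
  planted_genes <- unique(gm$variants$gene[gm$variants$planted])
  traits <- fhhnc_trait_list()
  rna <- stats::runif(length(genes)) < 0.7
  prot <- rna & (stats::runif(length(genes)) < 0.8)
  rna[genes %in% planted_genes] <- TRUE
  prot[genes %in% planted_genes] <- TRUE
  expression <- data.frame(gene = genes, rna_evidence = rna,
                           protein_evidence = prot, stringsAsFactors = FALSE)

  gwas_rows <- list()
  for (g in planted_genes) {
    gwas_rows[[length(gwas_rows) + 1L]] <- data.frame(
      variant_id = sprintf("rsG%05d", length(gwas_rows) + 1L), gene = g,
      trait = sample(traits, 1), p = 10^-stats::runif(1, 7, 12))
  }
  decoys <- sample(setdiff(genes, planted_genes),
                   ceiling(0.4 * length(genes)))
  for (g in decoys) {
    in_list <- stats::runif(1) < 0.5
    gwas_rows[[length(gwas_rows) + 1L]] <- data.frame(
      variant_id = sprintf("rsG%05d", length(gwas_rows) + 1L), gene = g,
      trait = if (in_list) sample(traits, 1) else "standing height",
      p = if (in_list && stats::runif(1) < 0.5) 10^-stats::runif(1, 7, 10)
          else 10^-stats::runif(1, 2, 5))
  }
  gwas <- do.call(rbind, gwas_rows)

  ids <- variant_ids(gm$variants)
  eqtl_idx <- unique(c(which(gm$variants$planted),
                       sample(nrow(gm$variants),
                              min(10L, nrow(gm$variants)))))
  eqtl <- data.frame(
    variant_id = ids[eqtl_idx], gene = gm$variants$gene[eqtl_idx],
    tissue = "kidney tubule",
    p = ifelse(gm$variants$planted[eqtl_idx], 10^-stats::runif(length(eqtl_idx), 8, 13),
               10^-stats::runif(length(eqtl_idx), 1, 4)),
    stringsAsFactors = FALSE)

  sets <- list()
  if (length(planted_genes)) {
    sets[["planted_modifier_pathway"]] <-
      unique(c(planted_genes, sample(genes, min(5L, length(genes)))))
  }
  for (k in seq_len(8)) {
    sets[[sprintf("random_set_%02d", k)]] <-
      sample(genes, min(length(genes), sample(5:15, 1)))
  }
  annotation_bundle(expression = expression, gwas = gwas, traits = traits,
                    eqtl = eqtl, gene_sets = sets)
}

simulate_reference_distribution <- function(gm, n_reference) {
  ids <- variant_ids(gm$variants)
  counts <- t(vapply(gm$variants$maf, function(q) {
    d <- stats::rbinom(n_reference, 2L, q)
    c(sum(d == 2), sum(d == 1), sum(d == 0))
  }, numeric(3)))
  data.frame(variant_id = ids, gene = gm$variants$gene,
             n_homalt = counts[, 1], n_het = counts[, 2],
             n_homref = counts[, 3], n = n_reference,
             stringsAsFactors = FALSE)
}

#' Curated disease-related trait list
#'
#' Traits used to match candidate genes against GWAS-catalog-style
#' associations: the renal progression trait plus the common symptom
#' spectrum of the disease and its ocular involvement. The list ships as
#' an editable plain-text file under `extdata/fhhnc_traits.txt`.
#' @param path optional path to an alternative trait file (one trait per
#'   line).
#' @export
fhhnc_trait_list <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "fhhnc_traits.txt",
                        package = "modifierscan")
  }
  traits <- readLines(path)
  traits[nzchar(trimws(traits))]
}
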