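#' Pipeline configuration
#'
#' Collects every stage's parameters and file locations. All thresholds
#' default to the values used in the modifier-discovery design this package
#' implements: impact MODERATE/HIGH with depth >= 10 in >= 1 sample, eGFR
#' fast-progression cutoff 10 mL/min/1.73m2/yr, gene-scan candidate
#' threshold p < 0.01, GWAS-catalog match at p < 1e-6, risk selection at
#' Fisher p < 0.05 with BH q < 0.15, ORA reporting at adjusted p < 0.25.
#'
#' @param input_dir directory with the pipeline inputs (`cohort.vcf`,
#'   `egfr.tsv`, annotation tables; see [write_cohort()]).
#' @param outdir output directory for intermediate tables and the report.
#' @param seed global RNG seed.
#' @param simulate `NULL` to consume existing inputs, or a list of
#'   [cohort_sim_config()] arguments to generate them into `input_dir`.
#' @param stratification,filter,skato,prioritization,risk,ora per-stage
#'   parameter lists (see the respective config constructors).
#' @param burden_range interval for the risk-allele burden summary.
#' @export
pipeline_config <- function(input_dir, outdir, seed = 1L, simulate = NULL,
                            stratification = list(fast_cutoff = 10,
                                                  stable_epsilon = 1),
                            filter = list(min_depth = 10, min_samples = 1),
                            skato = list(),
                            prioritization = list(),
                            risk = list(p_max = 0.05, q_max = 0.15),
                            ora = list(k = 15, padj_max = 0.25),
                            burden_range = c(9, 15)) {
  structure(list(input_dir = input_dir, outdir = outdir,
                 seed = as.integer(seed), simulate = simulate,
                 stratification = stratification, filter = filter,
                 skato = skato, prioritization = prioritization,
                 risk = risk, ora = ora, burden_range = burden_range),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

pipeline_stages <- function() {
  c("simulate", "stratify", "filter", "scan", "prioritize", "risk", "enrich")
}

#' Run the modifier-discovery pipeline
#'
#' Executes simulate (optional) -> stratify -> filter -> scan ->
#' prioritize -> risk -> enrich, writing every intermediate table under
#' `config$outdir` and a JSON + text run report with stage-wise counts.
#' Any stage failure aborts with the stage name; outputs of completed
#' stages are retained.
#'
#' @param config a [pipeline_config()] (or path to its YAML file).
#' @param stages subset of stages to run, in pipeline order; earlier
#'   results are re-read from `outdir`/`input_dir` when needed.
#' @return invisibly, the run report (a list), which is also written to
#'   `outdir/report.json` and `outdir/report.txt`.
#' @export
run_pipeline <- function(config, stages = pipeline_stages()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  if (!dir.exists(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE)
  }
  set.seed(config$seed)
  state <- new.env(parent = emptyenv())
  state$report <- list(seed = config$seed, config = unclass(config))
  for (stage in pipeline_stages()) {
    if (!stage %in% stages) next
    if (stage == "simulate" && is.null(config$simulate)) next
    tryCatch(
      switch(stage,
        simulate = stage_simulate(config, state),
        stratify = stage_stratify(config, state),
        filter = stage_filter(config, state),
        scan = stage_scan(config, state),
        prioritize = stage_prioritize(config, state),
        risk = stage_risk(config, state),
        enrich = stage_enrich(config, state)),
      error = function(e) {
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
  }
  report <- state$report
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(format_report(report), file.path(config$outdir, "report.txt"))
  invisible(report)
}

#' Run a single pipeline stage
#' @param stage one of `simulate`, `stratify`, `filter`, `scan`,
#'   `prioritize`, `risk`, `enrich`.
#' @param config a [pipeline_config()].
#' @export
run_stage <- function(stage, config) {
  run_pipeline(config, stages = stage)
}

need_file <- function(path, stage) {
  if (!file.exists(path)) {
    stop("required input not found: ", path)
  }
  path
}

out_tsv <- function(config, x, f) {
  utils::write.table(x, file.path(config$outdir, f), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

stage_simulate <- function(config, state) {
  sim_args <- config$simulate
  sim_args$seed <- config$seed
  cohort <- simulate_cohort(do.call(cohort_sim_config, sim_args))
  write_cohort(cohort, config$input_dir)
  state$cohort <- cohort
  state$report$simulate <- list(
    n_samples = length(cohort$genotypes$samples),
    n_variants = nrow(cohort$genotypes$variants),
    n_planted = nrow(cohort$ground_truth$planted))
  invisible(state)
}

stage_stratify <- function(config, state) {
  egfr <- utils::read.delim(
    need_file(file.path(config$input_dir, "egfr.tsv"), "stratify"))
  ov_path <- file.path(config$input_dir, "class_overrides.tsv")
  overrides <- if (file.exists(ov_path)) utils::read.delim(ov_path) else NULL
  calls <- assign_groups(egfr, overrides,
                         fast_cutoff = config$stratification$fast_cutoff,
                         stable_epsilon = config$stratification$stable_epsilon)
  out_tsv(config, calls, "progression_calls.tsv")
  state$calls <- calls
  state$report$stratify <- list(
    n_patients = nrow(calls),
    n_fast = sum(calls$group == "FAST"),
    n_nofast = sum(calls$group == "noFAST"))
  invisible(state)
}

stage_filter <- function(config, state) {
  gm <- parse_annotated_vcf(
    need_file(file.path(config$input_dir, "cohort.vcf"), "filter"))
  fgm <- filter_variants(gm, min_depth = config$filter$min_depth,
                         min_samples = config$filter$min_samples)
  grp <- group_by_gene(fgm)
  gene_report <- data.frame(
    gene = names(grp$groups),
    n_variants = vapply(grp$groups, length, 0L))
  out_tsv(config, gene_report, "gene_groups.tsv")
  state$gm <- fgm
  state$groups <- grp$groups
  state$report$filter <- list(
    variants_in = nrow(gm$variants),
    variants_out = nrow(fgm$variants),
    genes = length(grp$groups),
    unknown_gene_variants = length(grp$unknown))
  invisible(state)
}

stage_scan <- function(config, state) {
  if (is.null(state$gm)) stage_filter(config, state)
  if (is.null(state$calls)) stage_stratify(config, state)
  scan <- run_gene_scan(state$gm, state$calls,
                        do.call(skato_config, config$skato), state$groups)
  out_tsv(config, scan$results, "gene_scan.tsv")
  state$scan <- scan
  state$report$scan <- list(
    genes_tested = nrow(scan$results),
    genes_untestable = length(scan$untestable),
    genes_p_lt_0.05 = sum(scan$results$p < 0.05))
  invisible(state)
}

stage_prioritize <- function(config, state) {
  if (is.null(state$scan)) stage_scan(config, state)
  if (is.null(state$bundle)) {
    state$bundle <- read_annotation_bundle(config$input_dir)
  }
  pconf <- do.call(prioritization_config, config$prioritization)
  pri <- prioritize(state$scan$results, state$bundle, pconf, state$gm)
  out_tsv(config, pri, "prioritized_genes.tsv")
  state$prioritized <- pri
  state$report$prioritize <- as.list(c(
    total = nrow(pri),
    table(factor(pri$provenance,
                 c("round1", "round2_no_expression", "include_list")))))
  invisible(state)
}

stage_risk <- function(config, state) {
  if (is.null(state$prioritized)) stage_prioritize(config, state)
  keep <- state$gm$variants$gene %in% state$prioritized$gene
  if (!any(keep)) stop("no variants in prioritized genes")
  gm_pri <- genotype_matrix(state$gm$variants[keep, , drop = FALSE],
                            state$gm$samples,
                            state$gm$dosage[keep, , drop = FALSE],
                            if (is.null(state$gm$depth)) NULL else
                              state$gm$depth[keep, , drop = FALSE])
  results <- risk_variant_scan(gm_pri, state$calls)
  selected <- select_risk_variants(results, config$risk$p_max,
                                   config$risk$q_max)
  selected <- annotate_eqtl(selected, state$bundle)
  out_tsv(config, results, "risk_variants.tsv")
  out_tsv(config, selected, "risk_variants_selected.tsv")
  state$risk <- results
  state$selected <- selected
  state$report$risk <- list(variants_tested = nrow(results) / 2,
                            tests = nrow(results),
                            selected = nrow(selected))
  if (nrow(selected) > 0) {
    burden <- risk_allele_burden(gm_pri, selected, state$calls,
                                 range = config$burden_range)
    out_tsv(config, burden$per_patient, "risk_burden.tsv")
    out_tsv(config, burden$summary, "risk_burden_summary.tsv")
    state$burden <- burden
    state$report$burden <- lapply(seq_len(nrow(burden$summary)), function(i) {
      as.list(burden$summary[i, ])
    })
  }
  invisible(state)
}

stage_enrich <- function(config, state) {
  if (is.null(state$prioritized)) stage_prioritize(config, state)
  universe <- unique(c(names(state$groups),
                       unlist(state$bundle$gene_sets, use.names = FALSE)))
  ora <- hypergeometric_ora(state$prioritized$gene,
                            state$bundle$gene_sets, universe)
  report <- top_terms(ora, k = config$ora$k, padj_max = config$ora$padj_max)
  out_tsv(config, ora, "ora_results.tsv")
  out_tsv(config, report, "ora_top_terms.tsv")
  state$ora <- ora
  state$report$enrich <- list(sets_tested = nrow(ora),
                              sets_reported = nrow(report))
  invisible(state)
}

format_report <- function(report) {
  lines <- c("modifier-discovery pipeline report",
             paste0("seed: ", report$seed), "")
  for (stage in c("simulate", "stratify", "filter", "scan", "prioritize",
                  "risk", "burden", "enrich")) {
    if (is.null(report[[stage]])) next
    lines <- c(lines, paste0("[", stage, "]"))
    entry <- report[[stage]]
    if (stage == "burden") {
      for (g in entry) {
        lines <- c(lines, sprintf(
          "  %s: n=%d, burden min=%d max=%d, fraction in range=%.2f",
          g$group, g$n, g$min, g$max, g$frac_in_range))
      }
    } else {
      lines <- c(lines, paste0("  ", names(entry), ": ",
                               unlist(lapply(entry, paste, collapse = ","))))
    }
  }
  lines
}
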