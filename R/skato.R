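#' Fit the null phenotype model for the gene scan
#'
#' Logistic regression of the binary severe-progression indicator on an
#' intercept (optionally plus covariates). Residuals and variance weights
#' from this fit define the score statistics of every gene-level test.
#'
#' @param y binary phenotype vector (0 = noFAST, 1 = FAST), both classes
#'   present.
#' @param covariates optional numeric matrix/data.frame of per-sample
#'   covariates.
#' @return An object of class `skato_null`: list with `y`, `mu` (fitted
#'   means), `resid` (`y - mu`), `v` (`mu * (1 - mu)`) and the design
#'   matrix `X`.
#' @export
fit_null_model <- function(y, covariates = NULL) {
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("phenotype must be binary 0/1")
  if (length(unique(y)) < 2L) stop("degenerate phenotype: only one class present")
  n <- length(y)
  if (is.null(covariates)) {
    mu <- rep(mean(y), n)          # intercept-only closed form
    X <- matrix(1, n, 1)
  } else {
    X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    fit <- stats::glm.fit(X, y, family = stats::binomial())
    mu <- fit$fitted.values
  }
  structure(list(y = y, mu = mu, resid = y - mu, v = mu * (1 - mu), X = X),
            class = "skato_null")
}

#' Beta-density variant weights
#'
#' Standard rare-variant weighting: `dbeta(maf, a1, a2)`, upweighting rarer
#' variants with the default `(1, 25)`.
#'
#' @param maf minor-allele frequencies in `[0, 0.5]`.
#' @param a1,a2 positive shape parameters.
#' @export
beta_maf_weights <- function(maf, a1 = 1, a2 = 25) {
  stopifnot(a1 > 0, a2 > 0)
  stats::dbeta(maf, a1, a2)
}

#' Configuration of the SKAT-O gene-level test
#'
#' @param weight_beta length-2 shape parameters of the Beta MAF weight
#'   density (default `c(1, 25)`).
#' @param rho_grid mixing grid in `[0, 1]`; must contain 0 (pure SKAT) and
#'   1 (pure burden).
#' @param method `"analytic"` (eigen-based Davies-type p-values with
#'   moment-matching fallback) or `"permutation"` (label-permutation
#'   reference, recommended for very small cohorts).
#' @param n_permutations number of permutations for the permutation method.
#' @export
skato_config <- function(weight_beta = c(1, 25),
                         rho_grid = c(0, 0.1^2, 0.2^2, 0.3^2, 0.4^2, 0.5^2, 0.5, 1),
                         method = c("analytic", "permutation"),
                         n_permutations = 10000L) {
  method <- match.arg(method)
  stopifnot(length(weight_beta) == 2L, all(weight_beta > 0))
  rho_grid <- sort(unique(rho_grid))
  if (any(rho_grid < 0 | rho_grid > 1)) stop("rho_grid values must lie in [0, 1]")
  if (!(0 %in% rho_grid) || !(1 %in% rho_grid)) {
    stop("rho_grid must contain both 0 and 1")
  }
  structure(list(weight_beta = weight_beta, rho_grid = rho_grid,
                 method = method, n_permutations = as.integer(n_permutations)),
            class = "skato_config")
}

#' Unified rare-variant statistic at a fixed mixing parameter
#'
#' \eqn{Q_\rho = (1-\rho) Q_{SKAT} + \rho Q_{burden}} with
#' \eqn{Q_{SKAT} = \sum_j w_j^2 (g_j'r)^2} and
#' \eqn{Q_{burden} = (\sum_j w_j g_j' r)^2}, where `r` are the null-model
#' residuals.
#'
#' @param G samples x variants dosage matrix, no missing values.
#' @param weights per-variant weights.
#' @param null a `skato_null`.
#' @param rho mixing parameter in `[0, 1]`.
#' @return the non-negative statistic `Q`.
#' @export
rho_statistic <- function(G, weights, null, rho) {
  G <- as.matrix(G)
  stopifnot(inherits(null, "skato_null"), rho >= 0, rho <= 1,
            ncol(G) == length(weights), nrow(G) == length(null$resid))
  if (anyNA(G)) stop("missing dosages must be imputed before testing")
  if (ncol(G) < 1L) stop("at least one variant required")
  if (all(apply(G, 2, function(g) stats::var(g) == 0))) {
    stop("untestable gene: all variant dosages are constant")
  }
  u <- drop(crossprod(G, null$resid)) * weights
  (1 - rho) * sum(u^2) + rho * sum(u)^2
}

## P-projected weighted kernel K = W G' P G W with
## P = V - V X (X'VX)^{-1} X' V (V = diag(mu(1-mu)))
skato_kernel <- function(G, weights, null) {
  VG <- G * null$v
  VX <- null$X * null$v
  XtVX <- crossprod(null$X, VX)
  B <- crossprod(VX, G)                   # X' V G
  GPG <- crossprod(G, VG) - crossprod(B, solve(XtVX, B))
  K <- GPG * tcrossprod(weights)
  (K + t(K)) / 2
}

rho_kernel_eigen <- function(K, rho) {
  m <- nrow(K)
  if (m == 1L) return(drop(K))
  R <- (1 - rho) * diag(m) + rho * matrix(1, m, m)
  er <- eigen(R, symmetric = TRUE)
  Rh <- er$vectors %*% (sqrt(pmax(er$values, 0)) * t(er$vectors))
  A <- Rh %*% K %*% Rh
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev[ev > 1e-10 * max(ev)]
}

#' Gene-level SKAT-O test
#'
#' Computes the per-rho statistics and p-values over the configured grid and
#' the unified SKAT-O p-value for \eqn{T = \min_\rho p_\rho} by
#' one-dimensional numerical integration of its null distribution
#' (or, for `method = "permutation"`, a label-permutation minimum-p test).
#'
#' @param G samples x variants dosage matrix (no missing values).
#' @param null a `skato_null` fitted on the same samples.
#' @param config a [skato_config()].
#' @param maf optional per-variant MAFs used for the Beta weights; computed
#'   from `G` when omitted.
#' @return A list of class `gene_association_result`: `p` (unified p),
#'   `p_rho`, `Q_rho`, `rho_grid`, `rho_opt`, `n_variants`, `method`.
#' @export
skato_test <- function(G, null, config = skato_config(), maf = NULL) {
  G <- as.matrix(G)
  m <- ncol(G)
  if (m < 1L) stop("untestable gene: no variants")
  sds <- apply(G, 2, stats::sd)
  if (all(sds == 0)) stop("untestable gene: all variant dosages are constant")
  if (is.null(maf)) {
    af <- colMeans(G) / 2
    maf <- pmin(af, 1 - af)
  }
  w <- beta_maf_weights(maf, config$weight_beta[1], config$weight_beta[2])
  rho <- config$rho_grid
  Q <- vapply(rho, function(r) rho_statistic(G, w, null, r), 0)

  if (config$method == "permutation") {
    return(skato_permutation(G, w, null, rho, Q, config$n_permutations))
  }

  K <- skato_kernel(G, w, null)
  lam_rho <- lapply(rho, function(r) rho_kernel_eigen(K, r))
  p_rho <- vapply(seq_along(rho), function(i) {
    quad_form_pvalue(Q[i], lam_rho[[i]])$p
  }, 0)
  Tmin <- min(p_rho)
  i_opt <- which.min(p_rho)

  if (length(rho) == 1L || m == 1L) {
    ## single grid point, or a single variant (all Q_rho identical)
    p <- if (m == 1L) p_rho[[1L]] else Tmin
    return(structure(list(p = p, p_rho = p_rho, Q_rho = Q, rho_grid = rho,
                          rho_opt = rho[i_opt], n_variants = m,
                          method = "analytic"),
                     class = "gene_association_result"))
  }

  p <- skato_unified_p(K, rho, p_rho, lam_rho)
  structure(list(p = p, p_rho = p_rho, Q_rho = Q, rho_grid = rho,
                 rho_opt = rho[i_opt], n_variants = m, method = "analytic"),
            class = "gene_association_result")
}

## unified p-value for T = min_rho p_rho: decompose the statistic into a
## common burden direction (chi-square(1) variable x) plus the orthogonal
## mixture, and integrate the conditional acceptance probability over x.
skato_unified_p <- function(K, rho, p_rho, lam_rho) {
  m <- nrow(K)
  Tmin <- min(p_rho)
  one <- rep(1, m)
  B <- drop(K %*% one)               # K 1
  sK <- sum(B)                       # 1'K1
  if (sK <= 1e-12 * sum(diag(K))) {
    ## burden direction numerically null: fall back to Bonferroni over the grid
    return(min(1, Tmin * length(rho)))
  }
  zbar2 <- sK / m^2                  # ||zbar||^2
  cof1 <- B / m / zbar2              # projections of variant columns on zbar
  lam <- {
    Kres <- K - tcrossprod(B) / sK   # Z'(I - M)Z
    ev <- eigen((Kres + t(Kres)) / 2, symmetric = TRUE, only.values = TRUE)$values
    ev[ev > 1e-10 * max(ev, 0)]
  }
  tau <- vapply(rho, function(r) r * sK + (1 - r) * sum(B^2) / sK, 0)
  ## moments of the orthogonal remainder including the cross-term variance
  A1 <- tcrossprod(cof1) * zbar2           # Z1'Z1
  C12 <- outer(cof1, B / m)                # Z1'Z
  A2 <- K - C12 - t(C12) + A1              # Z2'Z2
  W33 <- 4 * sum(A1 * A2)
  MuQ <- sum(lam)
  VarQ <- 2 * sum(lam^2) + W33
  if (length(lam) == 0L || VarQ <= 0) return(min(1, Tmin * length(rho)))

  qmin <- vapply(seq_along(rho), function(i) {
    saddlepoint_quantile(Tmin, lam_rho[[i]])
  }, 0)
  rho_c <- pmin(rho, 1 - 1e-4)
  sd_adj <- sqrt(max(VarQ - W33, 0)) / sqrt(VarQ)

  integrand <- function(x) {
    vapply(x, function(xi) {
      kappa <- min((qmin - tau * xi) / (1 - rho_c))
      cdf <- if (kappa <= 0) {
        0
      } else if (kappa > MuQ + 200 * sqrt(VarQ)) {
        1
      } else {
        q_adj <- (kappa - MuQ) * sd_adj + MuQ
        if (q_adj <= 0) 0 else 1 - saddlepoint_tail(q_adj, lam)
      }
      cdf * stats::dchisq(xi, df = 1)
    }, 0)
  }
  int <- stats::integrate(integrand, 0, 40, subdivisions = 1000L,
                          rel.tol = 1e-7, abs.tol = 1e-10,
                          stop.on.error = FALSE)
  p <- 1 - int$value
  ## the minimum over the grid bounds p below; Bonferroni bounds it above
  min(max(p, Tmin), min(1, Tmin * length(rho)))
}

## permutation reference: empirical per-rho p-values under label permutation,
## minimum-p combined across the grid
skato_permutation <- function(G, w, null, rho, Q_obs, B) {
  n <- nrow(G)
  r <- null$resid
  Gw <- G * rep(w, each = n)
  perm <- matrix(r[vapply(seq_len(B), function(b) sample.int(n), integer(n))],
                 nrow = n)
  U <- crossprod(Gw, perm)                     # m x B
  Qs <- colSums(U^2)
  Qb <- colSums(U)^2
  K <- length(rho)
  p_rho_obs <- numeric(K)
  Tb <- rep(Inf, B)
  for (i in seq_len(K)) {
    Qi <- (1 - rho[i]) * Qs + rho[i] * Qb
    p_rho_obs[i] <- (1 + sum(Qi >= Q_obs[i])) / (B + 1)
    ## empirical survival of each permuted statistic among all permutations
    srt <- sort(Qi)
    pb <- (B - findInterval(Qi, srt) + 1) / B
    Tb <- pmin(Tb, pb)
  }
  Tmin <- min(p_rho_obs)
  p <- (1 + sum(Tb <= Tmin)) / (B + 1)
  structure(list(p = p, p_rho = p_rho_obs, Q_rho = Q_obs, rho_grid = rho,
                 rho_opt = rho[which.min(p_rho_obs)],
                 n_variants = ncol(G), method = "permutation"),
            class = "gene_association_result")
}

#' Benjamini-Hochberg adjustment
#'
#' Thin, validating wrapper around `p.adjust(method = "BH")`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Gene-level rare-variant association scan
#'
#' Runs [skato_test()] on every gene group of a filtered genotype matrix
#' against the FAST/noFAST grouping. Missing dosages are mean-imputed per
#' variant before testing; genes whose dosages are entirely constant are
#' reported as untestable.
#'
#' @param gm a `genotype_matrix` (see [parse_annotated_vcf()]).
#' @param calls a data frame with columns `patient_id` and `group`
#'   (`"FAST"`/`"noFAST"`), e.g. from [assign_groups()].
#' @param config a [skato_config()].
#' @param groups optional gene -> variant-index map from [group_by_gene()];
#'   computed from `gm` when omitted.
#' @return list with `results` (data frame: gene, n_variants, p, p_adj,
#'   rho_opt) sorted by p, and `untestable` (character vector of gene names).
#' @export
run_gene_scan <- function(gm, calls, config = skato_config(), groups = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!all(c("patient_id", "group") %in% names(calls))) {
    stop("calls must have patient_id and group columns")
  }
  if (!setequal(calls$patient_id, gm$samples)) {
    stop("sample-id mismatch between genotype matrix and phenotype calls")
  }
  y <- as.integer(calls$group[match(gm$samples, calls$patient_id)] == "FAST")
  null <- fit_null_model(y)
  if (is.null(groups)) groups <- group_by_gene(gm)$groups

  D <- impute_missing_dosages(gm$dosage)
  res <- list(); untestable <- character()
  for (gene in names(groups)) {
    idx <- groups[[gene]]
    G <- t(D[idx, , drop = FALSE])
    if (all(apply(G, 2, stats::sd) == 0)) {
      untestable <- c(untestable, gene)
      next
    }
    fit <- skato_test(G, null, config)
    res[[gene]] <- data.frame(gene = gene, n_variants = fit$n_variants,
                              p = fit$p, rho_opt = fit$rho_opt,
                              stringsAsFactors = FALSE)
  }
  if (length(res) == 0L) {
    return(list(results = data.frame(gene = character(), n_variants = integer(),
                                     p = numeric(), rho_opt = numeric(),
                                     p_adj = numeric()),
                untestable = untestable))
  }
  out <- do.call(rbind, res)
  out$p_adj <- adjust_pvalues(out$p)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  list(results = out, untestable = untestable)
}

## per-variant mean imputation (rows = variants)
impute_missing_dosages <- function(D) {
  nas <- which(is.na(D), arr.ind = TRUE)
  if (nrow(nas) > 0L) {
    mu <- rowMeans(D, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    D[nas] <- mu[nas[, 1]]
  }
  D
}
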