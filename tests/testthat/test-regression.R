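test_that("design validation prepends an intercept and checks rank and df", {
  x0 <- matrix(numeric(0), 10, 0)
  rownames(x0) <- paste0("s", 1:10)
  d <- validateDesign(x0)
  expect_equal(unname(d@base), matrix(1, 10, 1))
  expect_identical(colnames(d@base), "(Intercept)")
  expect_equal(d@rank, 1L)

  set.seed(1)
  x <- cbind(a = rnorm(10), b = rnorm(10))
  x <- cbind(x, c = 2 * x[, "a"])
  expect_error(validateDesign(x), "rank-deficient")

  x2 <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(validateDesign(x2), "non-positive residual degrees of freedom")
})

test_that("residualization matches the per-row least-squares oracle", {
  set.seed(2)
  n <- 8
  X <- cbind(a = rnorm(n), b = runif(n))
  d <- validateDesign(X)
  Y <- matrix(rnorm(6 * n), 6, n)
  R <- residualize(Y, d)
  for (i in 1:6) {
    oracle <- stats::residuals(stats::lm(Y[i, ] ~ X))
    expect_equal(unname(R[i, ]), unname(oracle), tolerance = 1e-10)
  }
  # residuals orthogonal to every design column
  expect_lt(max(abs(R %*% d@base)), 1e-10)

  # zero-mean row under intercept-only design is unchanged
  d0 <- validateDesign(matrix(numeric(0), n, 0))
  y0 <- rnorm(n); y0 <- y0 - mean(y0)
  expect_equal(as.numeric(residualize(rbind(y0), d0)), y0, tolerance = 1e-12)

  # a row that IS a design combination goes to zero
  comb <- rbind(3 + 2 * X[, "a"] - X[, "b"])
  expect_lt(max(abs(residualize(comb, d))), 1e-10)
})

test_that("noiseless construction is recovered exactly", {
  set.seed(3)
  n <- 20
  M <- rbind(cg1 = runif(n))
  Y <- rbind(g1 = 2 * M[1, ] + 3)
  colnames(Y) <- colnames(M) <- paste0("s", 1:n)
  d <- validateDesign(matrix(numeric(0), n, 0))
  res <- batchedMlr(Y, M, d)
  expect_equal(res$est[1, 1], 2, tolerance = 1e-10)
  expect_lt(res$p[1, 1], 1e-12)
  expect_equal(res$df, n - 2L)
})

test_that("batched regression matches the per-pair lm() oracle on a random block", {
  set.seed(4)
  n <- 50; G <- 20; C <- 30; m <- 3
  X <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("c", 1:m)))
  Y <- matrix(rnorm(G * n), G, n, dimnames = list(paste0("g", 1:G), NULL))
  M <- matrix(runif(C * n), C, n, dimnames = list(paste0("cg", 1:C), NULL))
  res <- batchedMlr(Y, M, validateDesign(X))
  for (k in sample(G, 6)) for (j in sample(C, 6)) {
    o <- lmPairOracle(Y[k, ], M[j, ], X)
    expect_equal(res$est[k, j], o$est, tolerance = 1e-8)
    expect_equal(res$se[k, j], o$se, tolerance = 1e-8)
    expect_equal(res$t[k, j], o$t, tolerance = 1e-8)
  }
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_equal(res$t, res$est / res$se)
  expect_equal(res$df, n - m - 2L)
})

test_that("per-covariate terms match the full-model lm() fit", {
  set.seed(5)
  n <- 40; m <- 2
  X <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, c("age", "batch")))
  Y <- matrix(rnorm(3 * n), 3, n, dimnames = list(paste0("g", 1:3), NULL))
  M <- matrix(runif(2 * n), 2, n, dimnames = list(paste0("cg", 1:2), NULL))
  res <- batchedMlr(Y, M, validateDesign(X), withCovariates = TRUE)
  for (k in 1:3) for (j in 1:2) {
    fit <- summary(stats::lm(Y[k, ] ~ X + M[j, ]))$coefficients
    expect_equal(res$cov_intercept_est[k, j], fit["(Intercept)", 1],
                 tolerance = 1e-8)
    expect_equal(res$cov_age_se[k, j], fit["Xage", 2], tolerance = 1e-8)
    expect_equal(res$cov_batch_t[k, j], fit["Xbatch", 3], tolerance = 1e-8)
  }
})

test_that("constant methylation rows yield sentinels without disturbing others", {
  set.seed(6)
  n <- 25
  Y <- matrix(rnorm(4 * n), 4, n, dimnames = list(paste0("g", 1:4), NULL))
  M <- rbind(cgA = runif(n), cgFlat = rep(0.5, n), cgB = runif(n))
  res <- withQuietLogs(batchedMlr(Y, M, validateDesign(matrix(numeric(0), n, 0))))
  expect_true(all(is.nan(res$est[, "cgFlat"])))
  expect_true(all(is.nan(res$p[, "cgFlat"])))
  expect_identical(res$degenerate_cpgs, "cgFlat")
  o <- lmPairOracle(Y[2, ], M["cgB", ])
  expect_equal(res$est[2, "cgB"], o$est, tolerance = 1e-10)
})

test_that("estimates obey affine-invariance laws", {
  set.seed(7)
  n <- 60
  X <- cbind(a = rnorm(n))
  Y <- matrix(rnorm(2 * n), 2, n, dimnames = list(c("g1", "g2"), NULL))
  M <- matrix(runif(2 * n), 2, n, dimnames = list(c("c1", "c2"), NULL))
  base <- batchedMlr(Y, M, validateDesign(X))
  # rescaling a covariate leaves everything unchanged
  resc <- batchedMlr(Y, M, validateDesign(cbind(a = 5 * X[, "a"] - 3)))
  expect_equal(resc$est, base$est, tolerance = 1e-10)
  expect_equal(resc$t, base$t, tolerance = 1e-10)
  # scaling M by c divides est by c; t and p invariant
  sc <- batchedMlr(Y, 4 * M, validateDesign(X))
  expect_equal(sc$est, base$est / 4, tolerance = 1e-10)
  expect_equal(sc$t, base$t, tolerance = 1e-10)
  # scaling Y and M together: t and p invariant
  sc2 <- batchedMlr(0.1 * Y, 7 * M, validateDesign(X))
  expect_equal(sc2$t, base$t, tolerance = 1e-10)
  expect_equal(sc2$p, base$p, tolerance = 1e-10)
})

test_that("Pearson block matches direct formulas and the regression identity", {
  set.seed(8)
  n <- 30
  Y <- matrix(rnorm(3 * n), 3, n, dimnames = list(paste0("g", 1:3), NULL))
  M <- matrix(runif(4 * n), 4, n, dimnames = list(paste0("c", 1:4), NULL))
  res <- pearsonBlock(Y, M)
  for (k in 1:3) for (j in 1:4)
    expect_equal(res$est[k, j], corPairOracle(Y[k, ], M[j, ]),
                 tolerance = 1e-12)
  # with no covariates the Pearson t equals the simple-regression t
  mlr <- batchedMlr(Y, M, validateDesign(matrix(numeric(0), n, 0)))
  expect_equal(res$t, mlr$t, tolerance = 1e-10)
  expect_equal(res$df, n - 2L)
})

test_that("perfect and degenerate correlations saturate deterministically", {
  n <- 12
  base <- runif(n)
  Y <- rbind(g1 = base, g2 = -base, g3 = rep(1, n))
  M <- rbind(c1 = base, c2 = runif(n))
  res <- withQuietLogs(pearsonBlock(Y, M))
  expect_equal(res$est["g1", "c1"], 1)
  expect_equal(res$t["g1", "c1"], 1e8)
  expect_equal(res$p["g1", "c1"], 0)
  expect_equal(res$est["g2", "c1"], -1)
  expect_equal(res$t["g2", "c1"], -1e8)
  expect_true(all(is.nan(res$est["g3", ])))
})

test_that("Gaussian two-sided p-values are exact, monotone, and tail-stable", {
  expect_equal(gaussianTwoSidedP(0), 1)
  expect_equal(gaussianTwoSidedP(1.959963985), 0.05, tolerance = 1e-6)
  # far tail: no catastrophic cancellation; still positive at t=37.5 (just
  # above the double underflow limit) and never negative or NaN beyond it
  p375 <- gaussianTwoSidedP(37.5)
  expect_gt(p375, 0)
  expect_lt(p375, 1e-300)
  expect_gte(gaussianTwoSidedP(40), 0)
  expect_false(is.nan(gaussianTwoSidedP(40)))
  expect_true(is.nan(gaussianTwoSidedP(NA)))
  expect_equal(gaussianTwoSidedP(Inf), 0)
  grid <- seq(0, 12, by = 0.01)
  p <- gaussianTwoSidedP(grid)
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(gaussianTwoSidedP(-2), gaussianTwoSidedP(2))
})
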